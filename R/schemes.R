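# The three nested classification vocabularies. Entering and exiting happen
# only while the net is unfurled, so the coarsest scheme folds them, with
# net_down, into a single "net in use" class; sleep and net_up survive every
# collapse unchanged.

#' Class scheme vocabularies
#'
#' @param scheme "five", "four" or "three".
#' @return Ordered character vector of output labels.
#' @export
scheme_classes <- function(scheme = c("five", "four", "three")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    five  = c("sleep", "net_down", "net_up", "enter", "exit"),
    four  = c("sleep", "net_down", "net_up", "enter_exit"),
    three = c("sleep", "net_up", "net_down_active")
  )
}

#' Collapse base behaviour labels into a classification scheme
#'
#' Maps the five base labels into one of the three nested vocabularies:
#' \describe{
#'   \item{five}{identity: sleep, net_down, net_up, enter, exit}
#'   \item{four}{enter and exit merge into \code{enter_exit}}
#'   \item{three}{net_down, enter and exit merge into \code{net_down_active}
#'     (all three occur only when the net is unfurled)}
#' }
#' Sleep and net_up are fixed points of every scheme. The three-category
#' mapping factors through the four-category one.
#'
#' @param labels Character vector or factor of base labels.
#' @param scheme "five", "four" or "three".
#' @return Factor over \code{scheme_classes(scheme)}.
#' @export
collapse_labels <- function(labels, scheme = c("five", "four", "three")) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), motion_labels())
  if (length(bad))
    stop("collapse_labels: unknown label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- switch(scheme,
    five = labels,
    four = ifelse(labels %in% c("enter", "exit"), "enter_exit", labels),
    three = ifelse(labels %in% c("net_down", "enter", "exit"),
                   "net_down_active", labels)
  )
  factor(out, levels = scheme_classes(scheme))
}
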