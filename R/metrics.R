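#' Build a 2x2 confusion matrix from label vectors
#'
#' Cross-tabulates actual against predicted binary labels. The positive
#' class must be named explicitly so that `tp`/`fn`/`fp`/`tn` are
#' unambiguous; the other observed label is the negative class.
#'
#' @param actual Character (or factor) vector of true labels.
#' @param predicted Character (or factor) vector of predicted labels,
#'   same length as `actual`.
#' @param positive The label treated as the positive class.
#' @return A `confusion_matrix` object: a list with counts `tp`, `fn`,
#'   `fp`, `tn` and the `positive`/`negative` class names.
#' @seealso [confusion_counts()] to build one directly from counts,
#'   [accuracy()], [mcc()].
#' @export
#' @examples
#' cm <- confusion_matrix(c("F", "F", "M"), c("F", "M", "M"), positive = "F")
#' accuracy(cm)
confusion_matrix <- function(actual, predicted, positive) {
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have the same length.", call. = FALSE)
  }
  labs <- unique(c(actual, predicted))
  if (length(labs) > 2) {
    stop("labels outside a binary set: ", paste(labs, collapse = ", "),
         call. = FALSE)
  }
  if (!positive %in% labs) {
    stop("positive class '", positive, "' not among observed labels.",
         call. = FALSE)
  }
  negative <- setdiff(labs, positive)
  if (length(negative) == 0) negative <- NA_character_
  confusion_counts(
    tp = sum(actual == positive & predicted == positive),
    fn = sum(actual == positive & predicted != positive),
    fp = sum(actual != positive & predicted == positive),
    tn = sum(actual != positive & predicted != positive),
    positive = positive, negative = negative
  )
}

#' Build a confusion matrix from its four counts
#'
#' @param tp,fn,fp,tn Non-negative counts (true positive, false negative,
#'   false positive, true negative).
#' @param positive,negative Optional class names carried for printing.
#' @return A `confusion_matrix` object.
#' @export
confusion_counts <- function(tp, fn, fp, tn,
                             positive = "positive", negative = "negative") {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers.", call. = FALSE)
  }
  if (sum(counts) == 0) stop("confusion matrix total must be > 0.", call. = FALSE)
  structure(
    list(tp = tp, fn = fn, fp = fp, tn = tn,
         positive = positive, negative = negative),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(actual = c(x$positive, x$negative),
                              predicted = c(x$positive, x$negative)))
  cat("Confusion matrix (positive = ", x$positive, ")\n", sep = "")
  print(m)
  cat(sprintf("accuracy %.4f, MCC %.4f\n", accuracy(x), mcc(x)))
  invisible(x)
}

#' Classification accuracy
#'
#' @param cm A `confusion_matrix`.
#' @return Proportion of correct calls, `(tp + tn) / total`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  (cm$tp + cm$tn) / (cm$tp + cm$fn + cm$fp + cm$tn)
}

#' Matthews correlation coefficient
#'
#' Balanced agreement measure for binary classification; equals the
#' Pearson correlation of the two binary label vectors. When any factor
#' under the square root is zero the coefficient is defined as 0.
#'
#' @param cm A `confusion_matrix`.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    actual = rep(c(x$positive, x$negative), each = 2),
    predicted = rep(c(x$positive, x$negative), times = 2),
    n = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    n = x$tp + x$fn + x$fp + x$tn,
    accuracy = accuracy(x),
    mcc = mcc(x)
  )
}
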