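#' Contingency table for segment-level cancer calls
#'
#' Cross-tabulates one observer's per-segment calls against the
#' histopathological gold standard.
#'
#' @param tp,fp,fn,tn non-negative integer counts: true positives
#'   (reader positive, pathology positive), false positives, false
#'   negatives, true negatives
#' @param observer_id label for the observer
#' @return a `contingency_table` object
#' @export
contingency_table <- function(tp, fp, fn, tn, observer_id = "") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 observer_id = observer_id),
            class = "contingency_table")
}

# round-half-away-from-zero, the convention of the printed tables
# (base round() rounds half to even)
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Diagnostic-accuracy metrics from a contingency table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive
#' predictive value `tp/(tp+fp)` and negative predictive value
#' `tn/(tn+fn)`. A zero denominator yields `NaN` with a warning.
#' Rounded values use round-half-away-from-zero to 2 decimals.
#'
#' @param ct a [contingency_table()]
#' @param digits decimals for the rounded values (default 2)
#' @return a `diagnostic_metrics` list with fields `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `rounded` (named vector) and
#'   `observer_id`
#' @examples
#' diagnostic_metrics(contingency_table(64, 19, 116, 217))$rounded
#' @export
diagnostic_metrics <- function(ct, digits = 2) {
  stopifnot(inherits(ct, "contingency_table"))
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    num / den
  }
  sens <- ratio(ct$tp, ct$tp + ct$fn, "sensitivity")
  spec <- ratio(ct$tn, ct$tn + ct$fp, "specificity")
  ppv <- ratio(ct$tp, ct$tp + ct$fp, "PPV")
  npv <- ratio(ct$tn, ct$tn + ct$fn, "NPV")
  vals <- c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv)
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
                 rounded = round_half_away(vals, digits),
                 observer_id = ct$observer_id),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat("Diagnostic metrics", if (nzchar(x$observer_id))
    paste0(" (", x$observer_id, ")"), "\n", sep = "")
  print(x$rounded)
  invisible(x)
}

#' Metrics table for a set of observers
#'
#' One row per observer with the four rounded metrics; ready to write
#' with [utils::write.csv()].
#'
#' @param cts a list of [contingency_table()]s
#' @param digits decimals for rounding
#' @return a data frame with columns `observer`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`
#' @export
metrics_table <- function(cts, digits = 2) {
  if (length(cts) == 0) stop("empty list of contingency tables", call. = FALSE)
  rows <- lapply(cts, function(ct) {
    m <- diagnostic_metrics(ct, digits)
    data.frame(observer = ct$observer_id,
               sensitivity = m$rounded[["sensitivity"]],
               specificity = m$rounded[["specificity"]],
               ppv = m$rounded[["ppv"]],
               npv = m$rounded[["npv"]])
  })
  do.call(rbind, rows)
}

#' Cross-tabulate per-segment labels into a contingency table
#'
#' @param truth_labels binary vector of histopathology per segment
#'   (1 = cancer present)
#' @param call_labels binary vector of the observer's calls, same length
#' @param observer_id label
#' @return a [contingency_table()]
#' @export
segments_from_labels <- function(truth_labels, call_labels, observer_id = "") {
  truth <- as.integer(truth_labels)
  calls <- as.integer(call_labels)
  if (length(truth) != length(calls))
    stop("truth and call vectors differ in length", call. = FALSE)
  if (!all(c(truth, calls) %in% c(0L, 1L)))
    stop("labels must be binary (0/1)", call. = FALSE)
  contingency_table(tp = sum(truth == 1 & calls == 1),
                    fp = sum(truth == 0 & calls == 1),
                    fn = sum(truth == 1 & calls == 0),
                    tn = sum(truth == 0 & calls == 0),
                    observer_id = observer_id)
}

#' Prostate segmentation scheme
#'
#' The reading scheme divides the prostate into transversal planes,
#' each split into sectors. The printed total of 28 segments is the
#' default; supplying `sectors_per_plane` overrides it with the sum of
#' the sectors (e.g. `c(8, 8, 8, 6)` gives 30).
#'
#' @param sectors_per_plane optional integer vector of sector counts
#' @param total_segments total used when `sectors_per_plane` is absent
#' @return a `segment_scheme` list with `n_planes`, `sectors_per_plane`
#'   and `total_segments`
#' @export
segment_scheme <- function(sectors_per_plane = NULL, total_segments = 28) {
  if (!is.null(sectors_per_plane)) {
    sectors_per_plane <- as.integer(sectors_per_plane)
    if (any(sectors_per_plane <= 0)) stop("sector counts must be positive",
                                          call. = FALSE)
    total_segments <- sum(sectors_per_plane)
  }
  structure(list(n_planes = if (is.null(sectors_per_plane)) 4L
                 else length(sectors_per_plane),
                 sectors_per_plane = sectors_per_plane,
                 total_segments = as.integer(total_segments)),
            class = "segment_scheme")
}

#' Read contingency tables from CSV
#'
#' Expects a header `observer,tp,fp,fn,tn`.
#'
#' @param path CSV path
#' @return a list of [contingency_table()]s
#' @export
read_contingency_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer", "tp", "fp", "fn", "tn")
  if (!all(need %in% names(df)))
    stop("contingency CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    contingency_table(df$tp[i], df$fp[i], df$fn[i], df$tn[i],
                      observer_id = df$observer[i]))
}
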