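#' Confusion counts of a binary prediction
#'
#' @param pred Binary 0/1 prediction vector.
#' @param truth Binary 0/1 truth vector of the same length.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` must have equal length.")
  }
  if (length(pred) < 1L) abort("Need at least one sample.")
  if (!all(pred %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L))) {
    abort("`pred` and `truth` must be binary 0/1.")
  }
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  structure(
    list(
      tp = sum(pred == 1L & truth == 1L),
      fp = sum(pred == 1L & truth == 0L),
      tn = sum(pred == 0L & truth == 0L),
      fn = sum(pred == 0L & truth == 1L)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

safe_ratio <- function(num, den) {
  if (den > 0) list(value = num / den, defined = TRUE) else list(value = 0, defined = FALSE)
}

#' Six-measure evaluation of a confusion table
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy,
#' precision `TP/(TP+FP)`, F-measure (harmonic mean of sensitivity and
#' precision), and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Measures with a
#' degenerate (zero) denominator are reported as 0 with their `_defined` flag
#' set to `FALSE`; a zero MCC denominator (an empty marginal) likewise gives
#' MCC 0, the random-guess value.
#'
#' @param cm A [confusion()] result, or a list/vector with components
#'   `tp`, `fp`, `tn`, `fn`.
#' @return One-row tibble with columns `sen`, `spec`, `acc`, `prec`, `f1`
#'   (all in `[0, 1]`), `mcc` (in `[-1, 1]`), and logical `*_defined` flags.
#' @export
#' @examples
#' metrics(confusion(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1)))
metrics <- function(cm) {
  if (!inherits(cm, "confusion_counts")) {
    cm <- structure(as.list(cm)[c("tp", "fp", "tn", "fn")], class = "confusion_counts")
  }
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  tn <- as.numeric(cm$tn); fn <- as.numeric(cm$fn)
  if (any(c(tp, fp, tn, fn) < 0)) abort("Confusion counts must be non-negative.")
  total <- tp + fp + tn + fn
  if (total < 1) abort("Confusion table is empty.")
  sen <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  prec <- safe_ratio(tp, tp + fp)
  acc <- list(value = (tp + tn) / total, defined = TRUE)
  f1 <- if (sen$defined && prec$defined && (sen$value + prec$value) > 0) {
    list(value = 2 * sen$value * prec$value / (sen$value + prec$value), defined = TRUE)
  } else {
    list(value = 0, defined = FALSE)
  }
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den2 > 0) {
    list(value = (tp * tn - fp * fn) / sqrt(den2), defined = TRUE)
  } else {
    list(value = 0, defined = FALSE)
  }
  vals <- list(sen = sen, spec = spec, acc = acc, prec = prec, f1 = f1, mcc = mcc)
  out <- tibble::as_tibble(lapply(vals, `[[`, "value"))
  flags <- lapply(vals, `[[`, "defined")
  names(flags) <- paste0(names(vals), "_defined")
  dplyr::bind_cols(out, tibble::as_tibble(flags))
}

#' Amino-acid interface propensities
#'
#' For each standard amino acid, the log2 ratio of its within-class frequency
#' among interface residues to that among non-interface residues. Positive
#' values mark interface-enriched amino acids. When an amino acid has a zero
#' count in either class, add-one smoothing is applied to both of its class
#' counts and the row is flagged.
#'
#' @param aas Character vector of one-letter residue codes.
#' @param labels Binary 0/1 interface labels of the same length.
#' @return Tibble `aa, n_interface, n_non_interface, freq_interface,
#'   freq_non_interface, log2_propensity, smoothed`.
#' @export
propensity <- function(aas, labels) {
  if (length(aas) != length(labels)) abort("`aas` and `labels` must agree in length.")
  if (!any(labels == 1L) || !any(labels == 0L)) {
    abort("Both interface and non-interface residues are required.")
  }
  aa <- aa_order()
  unknown <- setdiff(unique(aas), aa)
  if (length(unknown)) {
    warn(sprintf(
      "Ignoring non-standard residue code(s): %s.", paste(unknown, collapse = ", ")
    ))
    keep <- aas %in% aa
    aas <- aas[keep]
    labels <- labels[keep]
  }
  n_pos <- unname(vapply(aa, function(a) sum(aas == a & labels == 1L), numeric(1)))
  n_neg <- unname(vapply(aa, function(a) sum(aas == a & labels == 0L), numeric(1)))
  smoothed <- n_pos == 0 | n_neg == 0
  cp <- ifelse(smoothed, n_pos + 1, n_pos)
  cn <- ifelse(smoothed, n_neg + 1, n_neg)
  fp_ <- cp / sum(cp)
  fn_ <- cn / sum(cn)
  tibble::tibble(
    aa = aa,
    n_interface = as.integer(n_pos),
    n_non_interface = as.integer(n_neg),
    freq_interface = fp_,
    freq_non_interface = fn_,
    log2_propensity = log2(fp_ / fn_),
    smoothed = smoothed
  )
}

#' Sensitivity-ordered performance curve tables
#'
#' Reorders a threshold sweep by increasing sensitivity and extracts the
#' sensitivity-precision and sensitivity-MCC curves (no interpolation).
#'
#' @param sweep A [threshold_sweep()] tibble.
#' @return List of two tibbles, `sens_precision` and `sens_mcc`.
#' @export
curve_table <- function(sweep) {
  if (nrow(sweep) < 1L) abort("`sweep` must have at least one row.")
  ord <- dplyr::arrange(sweep, .data$sen)
  list(
    sens_precision = dplyr::select(ord, "TH", "sen", "prec"),
    sens_mcc = dplyr::select(ord, "TH", "sen", "mcc")
  )
}
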