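# Tabular and FASTA interfaces. All tables are tab-separated with a header;
# sequence-profile tables carry one column per amino acid in the canonical
# ordering.

profile_cols <- function() c("chain_id", "position", "aa", aa_order())

#' Read chain sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of sequences (names are chain ids).
#' @export
read_chain_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write chain sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_chain_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a per-residue sequence-profile table
#'
#' Tab-separated with columns `chain_id, position, aa` followed by the 20
#' amino-acid frequency columns in canonical order.
#'
#' @param path Input TSV.
#' @return Tibble in the same layout.
#' @export
read_profile_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(profile_cols(), names(df))
  if (length(missing)) {
    abort(sprintf(
      "Profile table lacks column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  df[, profile_cols()]
}

#' Write a per-residue sequence-profile table
#'
#' @param profiles Tibble in [read_profile_table()] layout.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  readr::write_tsv(profiles[, profile_cols()], path, progress = FALSE)
  invisible(path)
}

#' Assemble chain profiles from a profile table
#'
#' Groups a profile table by chain and builds one [chain_profile()] per
#' chain, optionally checking sequences against a FASTA-derived named vector.
#'
#' @param profiles Tibble in [read_profile_table()] layout.
#' @param sequences Optional named character vector of chain sequences to
#'   validate against.
#' @return Named list of `chain_profile` objects.
#' @export
profiles_to_chains <- function(profiles, sequences = NULL) {
  split_df <- split(profiles, profiles$chain_id)
  chains <- lapply(split_df, function(df) {
    df <- df[order(df$position), ]
    if (!identical(as.integer(df$position), seq_len(nrow(df)))) {
      abort(sprintf(
        "Chain '%s': positions must be 1..n without gaps.", df$chain_id[1L]
      ))
    }
    seq_chr <- paste(df$aa, collapse = "")
    chain_profile(df$chain_id[1L], seq_chr, as.matrix(df[, aa_order()]))
  })
  if (!is.null(sequences)) {
    for (id in names(chains)) {
      if (!id %in% names(sequences)) {
        abort(sprintf("Chain '%s' absent from the FASTA sequences.", id))
      }
      if (!identical(chains[[id]]$sequence, unname(sequences[[id]]))) {
        abort(sprintf("Chain '%s': profile residues disagree with FASTA.", id))
      }
    }
  }
  chains
}

#' Read a delta-ASA / label table
#'
#' Tab-separated `chain_id, position, aa, delta_asa[, label]`. When `label`
#' is absent it is derived with [label_interface()]. When present it is
#' checked for consistency with the labeling rule.
#'
#' @param path Input TSV.
#' @return Tibble `chain_id, position, aa, delta_asa, label`.
#' @export
read_dasa_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chain_id", "position", "aa", "delta_asa")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf(
      "Delta-ASA table lacks column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  if (!"label" %in% names(df)) {
    df$label <- label_interface(df$delta_asa)
  } else if (!all(df$label == label_interface(df$delta_asa))) {
    abort("Stored labels contradict the > 1 A^2 delta-ASA rule.")
  }
  df$label <- as.integer(df$label)
  df[, c(need, "label")]
}

#' Write a delta-ASA / label table
#'
#' @param labels Tibble `chain_id, position, aa, delta_asa, label`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_dasa_table <- function(labels, path) {
  readr::write_tsv(
    labels[, c("chain_id", "position", "aa", "delta_asa", "label")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Write an encoded feature matrix
#'
#' Tab-separated `chain_id, position, v_1..v_L[, target]`.
#'
#' @param features Encoded feature tibble (see [encode_chain()]), optionally
#'   with a `target` column.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}

#' Read/write a chain-level cross-validation split
#'
#' @param folds Tibble `chain_id, fold`.
#' @param path TSV path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_cv_split <- function(folds, path) {
  readr::write_tsv(folds[, c("chain_id", "fold")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cv_split
#' @export
read_cv_split <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  df$fold <- as.integer(df$fold)
  df[, c("chain_id", "fold")]
}

#' Write a threshold-sweep metrics report
#'
#' Emits `TH, Sen, Spec, Acc, MCC, Prec, F1` with the five rate measures as
#' percentages rounded to 2 decimals and MCC as a value in `[-1, 1]` rounded
#' to 4 decimals.
#'
#' @param sweep A [threshold_sweep()] tibble.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(sweep, path) {
  out <- tibble::tibble(
    TH = sweep$TH,
    Sen = round(100 * sweep$sen, 2),
    Spec = round(100 * sweep$spec, 2),
    Acc = round(100 * sweep$acc, 2),
    MCC = round(sweep$mcc, 4),
    Prec = round(100 * sweep$prec, 2),
    F1 = round(100 * sweep$f1, 2)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a per-neuron cluster report
#'
#' @param selection A [select_clusters()] result.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(selection, path) {
  readr::write_tsv(cluster_report(selection), path, progress = FALSE)
  invisible(path)
}

#' Write per-residue predictions
#'
#' Tab-separated `chain_id, position, aa, votes, predicted` where `votes`
#' counts positive member outputs and `predicted` applies the threshold.
#'
#' @param meta Tibble with `chain_id`, `position`, `aa` rows matching `votes`.
#' @param votes Binary `n x K` vote matrix.
#' @param TH Vote threshold used for the `predicted` column.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(meta, votes, TH, path) {
  predicted <- combine_votes(votes, TH)
  out <- tibble::tibble(
    chain_id = meta$chain_id,
    position = meta$position,
    aa = meta$aa,
    votes = as.integer(rowSums(votes)),
    predicted = predicted
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
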