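# Peptide dataset input/output, validation, merging, folds and length strata.
#
# A "manifest" is a tibble with columns id, sequence, label, source. Labels
# are integer 1 (antioxidant peptide) / 0 (non-AOP), or NA when unknown.

new_manifest <- function(id, sequence, label, source, name = NULL) {
  out <- tibble::tibble(
    id = as.character(id),
    sequence = as.character(sequence),
    label = as.integer(label),
    source = as.character(source)
  )
  attr(out, "manifest_name") <- name
  out
}

#' Validate a peptide manifest
#'
#' Checks that every sequence uses only the 20 standard one-letter codes and
#' lies within the supported length range (2 to 50 residues, the fixed model
#' input length). Sequences are upper-cased. Failing records raise errors that
#' name the offending ids; nothing is silently dropped.
#'
#' @param data A data frame with at least a `sequence` column; `id`, `label`
#'   and `source` columns are used when present.
#' @param truncate If `TRUE`, sequences longer than `max_length` are clipped
#'   to their first `max_length` residues (with a message) instead of
#'   raising an error.
#' @param max_length Maximum allowed sequence length.
#' @param name Optional dataset name stored as an attribute.
#' @return A validated manifest tibble with columns `id`, `sequence`,
#'   `label`, `source`.
#' @export
#' @examples
#' validate_peptides(data.frame(sequence = c("GG", "ac"), label = c(1, 0)))
validate_peptides <- function(data, truncate = FALSE,
                              max_length = MAX_PEPTIDE_LENGTH, name = NULL) {
  stopifnot(is.data.frame(data))
  if (!"sequence" %in% names(data)) {
    stop_aopred("`data` must contain a `sequence` column.", "aopred_config_error")
  }
  n <- nrow(data)
  id <- if ("id" %in% names(data)) as.character(data$id) else as.character(seq_len(n))
  if (anyDuplicated(id)) {
    stop_aopred(
      paste0(
        "Duplicate record ids: ",
        paste(unique(id[duplicated(id)]), collapse = ", ")
      ),
      "aopred_validation_error"
    )
  }
  sequence <- toupper(trimws(as.character(data$sequence)))
  label <- if ("label" %in% names(data)) data$label else rep(NA_integer_, n)
  if (!all(is.na(label) | label %in% c(0, 1))) {
    bad <- id[!(is.na(label) | label %in% c(0, 1))]
    stop_aopred(
      paste0(
        "Labels must be 0, 1 or NA; offending ids: ",
        paste(head(bad, 10), collapse = ", ")
      ),
      "aopred_validation_error"
    )
  }
  source <- if ("source" %in% names(data)) as.character(data$source) else {
    rep(name %||% NA_character_, n)
  }

  bad_chr <- vapply(
    strsplit(sequence, ""),
    function(ch) paste(sort(unique(setdiff(ch, AA_ALPHABET))), collapse = ""),
    character(1)
  )
  if (any(nzchar(bad_chr))) {
    idx <- which(nzchar(bad_chr))
    stop_aopred(
      paste0(
        "Non-standard residue characters found: ",
        paste(
          sprintf("%s (%s)", id[idx][seq_len(min(10, length(idx)))],
                  bad_chr[idx][seq_len(min(10, length(idx)))]),
          collapse = ", "
        )
      ),
      "aopred_validation_error"
    )
  }

  len <- nchar(sequence)
  if (any(len > max_length)) {
    if (truncate) {
      idx <- which(len > max_length)
      inform(sprintf(
        "Truncating %d sequence(s) longer than %d residues: %s",
        length(idx), max_length, paste(head(id[idx], 5), collapse = ", ")
      ))
      sequence[idx] <- substr(sequence[idx], 1L, max_length)
      len <- nchar(sequence)
    } else {
      stop_aopred(
        paste0(
          "Sequences longer than ", max_length, " residues: ",
          paste(head(id[len > max_length], 10), collapse = ", "),
          ". Use `truncate = TRUE` to clip."
        ),
        "aopred_validation_error"
      )
    }
  }
  if (any(len < MIN_PEPTIDE_LENGTH)) {
    stop_aopred(
      paste0(
        "Sequences shorter than ", MIN_PEPTIDE_LENGTH, " residues: ",
        paste(head(id[len < MIN_PEPTIDE_LENGTH], 10), collapse = ", ")
      ),
      "aopred_validation_error"
    )
  }
  new_manifest(id, sequence, label, source, name = name)
}

#' Summary counts of a manifest
#'
#' @param manifest A manifest tibble.
#' @return A named integer vector with `n_pos`, `n_neg`, `n_unlabeled`.
#' @export
manifest_counts <- function(manifest) {
  c(
    n_pos = sum(manifest$label == 1, na.rm = TRUE),
    n_neg = sum(manifest$label == 0, na.rm = TRUE),
    n_unlabeled = sum(is.na(manifest$label))
  )
}

#' Read a peptide dataset from FASTA
#'
#' Labels are parsed from a `key=value` token on the description line, e.g.
#' `>pep1 label=1`. The record id is the first whitespace-delimited token.
#'
#' @param path Path to a FASTA file.
#' @param label_field Name of the description-line token carrying the binary
#'   label; set to `NULL` to skip label parsing.
#' @param truncate Passed to [validate_peptides()].
#' @return A validated manifest tibble.
#' @export
read_peptide_fasta <- function(path, label_field = "label", truncate = FALSE) {
  if (!file.exists(path)) {
    stop_aopred(paste0("File not found: ", path), "aopred_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) {
    return(new_manifest(character(), character(), integer(), character(),
                        name = basename(path)))
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop_aopred(
      sprintf("Malformed FASTA: line %d does not start a record ('>').",
              nonempty[1]),
      "aopred_parse_error"
    )
  }
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  id <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  label <- rep(NA_integer_, length(seqs))
  if (!is.null(label_field)) {
    pat <- paste0("(?:^|\\s)", label_field, "=([^\\s]+)")
    has <- grepl(pat, headers, perl = TRUE)
    val <- sub(pat, "\\1", regmatches(headers, regexpr(pat, headers, perl = TRUE)),
               perl = TRUE)
    if (length(val) && !all(val %in% c("0", "1"))) {
      stop_aopred(
        paste0("FASTA labels must be 0 or 1; got: ",
               paste(unique(setdiff(val, c("0", "1"))), collapse = ", ")),
        "aopred_validation_error"
      )
    }
    label[has] <- as.integer(val)
  }
  validate_peptides(
    tibble::tibble(
      id = id, sequence = as.character(seqs), label = label,
      source = basename(path)
    ),
    truncate = truncate, name = basename(path)
  )
}

#' Read a peptide dataset from a delimited table
#'
#' The delimiter (comma, tab or semicolon) is sniffed from the header row.
#' Row order is preserved; when no id column exists, row indices are used.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param seq_col,label_col,id_col Column names for the sequence, label and
#'   id. `label_col`/`id_col` may be absent from the file.
#' @param truncate Passed to [validate_peptides()].
#' @return A validated manifest tibble.
#' @export
read_peptide_table <- function(path, seq_col = "sequence", label_col = "label",
                               id_col = "id", truncate = FALSE) {
  if (!file.exists(path)) {
    stop_aopred(paste0("File not found: ", path), "aopred_io_error")
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  delims <- c(",", "\t", ";")
  counts <- vapply(delims, function(d) {
    m <- gregexpr(d, header, fixed = TRUE)[[1]]
    if (identical(m[1], -1L)) 0L else length(m)
  }, integer(1))
  delim <- if (all(counts == 0)) "," else delims[which.max(counts)]
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols(.default = "c"))
  if (!seq_col %in% names(df)) {
    stop_aopred(
      sprintf("Column '%s' not found in %s (columns: %s).", seq_col, path,
              paste(names(df), collapse = ", ")),
      "aopred_config_error"
    )
  }
  n <- nrow(df)
  label <- if (label_col %in% names(df)) {
    raw <- df[[label_col]]
    ok <- is.na(raw) | raw %in% c("0", "1")
    if (!all(ok)) {
      stop_aopred(
        paste0("Labels must be 0 or 1; offending rows: ",
               paste(head(which(!ok), 10), collapse = ", ")),
        "aopred_validation_error"
      )
    }
    as.integer(raw)
  } else {
    rep(NA_integer_, n)
  }
  id <- if (!is.null(id_col) && id_col %in% names(df)) df[[id_col]] else seq_len(n)
  validate_peptides(
    tibble::tibble(id = id, sequence = df[[seq_col]], label = label,
                   source = basename(path)),
    truncate = truncate, name = basename(path)
  )
}

#' Write a manifest to CSV or FASTA
#'
#' @param manifest A manifest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(manifest, path) {
  readr::write_csv(manifest[, c("id", "sequence", "label", "source")], path)
  invisible(path)
}

#' @rdname write_peptide_table
#' @param label_field Description-line token name used for labels.
#' @export
write_peptide_fasta <- function(manifest, path, label_field = "label") {
  hdr <- ifelse(
    is.na(manifest$label),
    manifest$id,
    paste0(manifest$id, " ", label_field, "=", manifest$label)
  )
  writeLines(paste0(">", hdr, "\n", manifest$sequence), path)
  invisible(path)
}

#' Merge peptide datasets
#'
#' Concatenates manifests, preserving source tags. With `deduplicate = TRUE`
#' records sharing a sequence collapse to the first occurrence; sequences
#' whose duplicates disagree on the label trigger a warning and are excluded
#' entirely when `drop_conflicts = TRUE`.
#'
#' @param manifests A list of manifest tibbles (or a single manifest).
#' @param deduplicate Collapse duplicated sequences to the first occurrence.
#' @param drop_conflicts With `deduplicate`, drop sequences with conflicting
#'   labels instead of keeping the first occurrence.
#' @return A merged manifest tibble.
#' @export
merge_datasets <- function(manifests, deduplicate = FALSE,
                           drop_conflicts = FALSE) {
  if (is.data.frame(manifests)) manifests <- list(manifests)
  if (length(manifests) < 1) {
    stop_aopred("Need at least one manifest.", "aopred_config_error")
  }
  merged <- dplyr::bind_rows(manifests)
  if (anyDuplicated(merged$id)) {
    merged$id <- make.unique(merged$id, sep = "_")
  }
  if (!deduplicate) {
    return(new_manifest(merged$id, merged$sequence, merged$label, merged$source,
                        name = "merged"))
  }
  by_seq <- split(seq_len(nrow(merged)), merged$sequence)
  conflict_seqs <- names(by_seq)[vapply(
    by_seq,
    function(ix) dplyr::n_distinct(merged$label[ix], na.rm = TRUE) > 1,
    logical(1)
  )]
  if (length(conflict_seqs)) {
    warn(paste0(
      "Label conflicts among duplicated sequences: ",
      paste(head(conflict_seqs, 10), collapse = ", "),
      if (length(conflict_seqs) > 10) " ..." else "",
      if (drop_conflicts) " (dropped)" else " (first occurrence kept)"
    ))
  }
  keep <- !duplicated(merged$sequence)
  if (drop_conflicts && length(conflict_seqs)) {
    keep <- keep & !(merged$sequence %in% conflict_seqs)
  }
  out <- merged[keep, ]
  new_manifest(out$id, out$sequence, out$label, out$source, name = "merged")
}

#' Stratified cross-validation folds
#'
#' Records are shuffled within each label class under a derived seed and
#' dealt round-robin into `k` folds, so per-fold class balance is within one
#' record of the global balance and fold sizes differ by at most one.
#'
#' @param manifest A labeled manifest tibble.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return An integer vector of fold indices in `1..k`, one per record, in
#'   manifest row order.
#' @export
make_folds <- function(manifest, k = 5, seed = 1) {
  if (k < 2) stop_aopred("k must be >= 2.", "aopred_config_error")
  if (k > nrow(manifest)) {
    stop_aopred("k exceeds the number of records.", "aopred_config_error")
  }
  if (anyNA(manifest$label)) {
    stop_aopred("make_folds requires a fully labeled manifest.",
                "aopred_config_error")
  }
  assignment <- integer(nrow(manifest))
  cursor <- 0L
  with_seed(derive_seed(seed, "folds"), {
    for (cls in sort(unique(manifest$label), decreasing = TRUE)) {
      idx <- which(manifest$label == cls)
      idx <- idx[sample.int(length(idx))]
      # continue dealing where the previous class stopped so that total fold
      # sizes stay within one of each other
      folds <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
      assignment[idx] <- folds
      cursor <- (cursor + length(idx)) %% k
    }
  })
  assignment
}

#' Split a manifest by peptide length
#'
#' Sequences shorter than `threshold` residues go into the `short` stratum,
#' all others (length >= threshold) into `long`; mirrors the short/long
#' peptide ablation at the 15-residue secondary-structure threshold.
#'
#' @param manifest A manifest tibble.
#' @param threshold Length threshold (inclusive on the long side).
#' @return A named list of two manifests, `short` and `long`.
#' @export
split_by_length <- function(manifest, threshold = 15) {
  if (threshold < 1) stop_aopred("threshold must be >= 1.", "aopred_config_error")
  len <- nchar(manifest$sequence)
  list(short = manifest[len < threshold, ], long = manifest[len >= threshold, ])
}

#' Maximum pairwise identity of query peptides against a reference set
#'
#' For each query sequence, computes the global (Needleman-Wunsch) alignment
#' against every reference sequence under match = 1, mismatch = 0,
#' gap = -1 scoring, takes identity = matched positions / alignment length,
#' and reports the maximum over references. The mean of the per-query maxima
#' is attached as the `mean_identity` attribute.
#'
#' @param query,reference Manifest tibbles (both non-empty).
#' @return A tibble with columns `id`, `identity` (percent, 0-100).
#' @export
pairwise_identity <- function(query, reference) {
  if (nrow(query) == 0 || nrow(reference) == 0) {
    stop_aopred("Both manifests must be non-empty.", "aopred_config_error")
  }
  submat <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(submat) <- 1
  ref <- Biostrings::AAStringSet(reference$sequence)
  best <- vapply(query$sequence, function(q) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = ref, subject = Biostrings::AAString(q), type = "global",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 1
    )
    pat <- as.character(Biostrings::alignedPattern(aln))
    sub <- as.character(Biostrings::alignedSubject(aln))
    ident <- vapply(seq_along(pat), function(i) {
      a <- strsplit(pat[i], "")[[1]]
      b <- strsplit(sub[i], "")[[1]]
      100 * sum(a == b & a != "-") / length(a)
    }, numeric(1))
    max(ident)
  }, numeric(1), USE.NAMES = FALSE)
  out <- tibble::tibble(id = query$id, identity = best)
  attr(out, "mean_identity") <- mean(best)
  out
}
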