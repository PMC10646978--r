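# Candidate-library ingestion, fingerprints and similarity analytics.

#' Load a candidate molecule library from CSV
#'
#' Reads a CSV with one molecule per row, canonicalizes every SMILES (2D
#' topology: stereochemistry flags are stripped), encodes each molecule as a
#' SELFIES-style token sequence, and flags (without dropping) rows whose
#' SMILES cannot be parsed or encoded.  Duplicate detection is by canonical
#' SMILES of the full multi-component entity.
#'
#' @param path CSV file path. Must have a header row.
#' @param smiles_column name of the SMILES column.
#' @param id_column optional name of an id column; when `NULL`, ids
#'   `"mol_<row>"` are generated deterministically from row order.
#' @param vendor_column optional name of a source-library column.
#' @param encode_selfies tokenize molecules at load (default `TRUE`); turn
#'   off to ingest large libraries quickly when only fingerprints are needed.
#' @return a `candidate_library`: a data.frame with columns `id`, `smiles`
#'   (canonical), `input_smiles`, `vendor`, `n_components`, `selfies_ok`,
#'   `duplicate`, a `selfies` list-column of token vectors, and attributes
#'   `rejects` (data.frame of unparseable rows) and `tested_ids`.
#' @export
load_library <- function(path, smiles_column = "smiles", id_column = NULL,
                         vendor_column = NULL, encode_selfies = TRUE) {
  if (!file.exists(path)) stop("library file not found: ", path)
  raw <- data.table::fread(path, colClasses = "character", data.table = FALSE)
  if (!smiles_column %in% names(raw)) {
    stop("configuration error: SMILES column '", smiles_column, "' not in file")
  }
  if (!is.null(id_column) && !id_column %in% names(raw)) {
    stop("configuration error: id column '", id_column, "' not in file")
  }
  smiles_in <- raw[[smiles_column]]
  ids <- if (is.null(id_column)) sprintf("mol_%d", seq_len(nrow(raw))) else raw[[id_column]]
  if (anyDuplicated(ids)) stop("molecule ids are not unique")
  vendor <- if (!is.null(vendor_column) && vendor_column %in% names(raw)) {
    raw[[vendor_column]]
  } else rep(NA_character_, nrow(raw))
  build_library(smiles_in, ids, vendor, encode_selfies = encode_selfies)
}

#' Assemble a candidate library from vectors (internal workhorse)
#' @keywords internal
build_library <- function(smiles_in, ids, vendor = NULL,
                          encode_selfies = TRUE) {
  can <- canonical_smiles(smiles_in, strip_stereo = TRUE)
  ok <- !is.na(can)
  rejects <- data.frame(row = which(!ok), id = ids[!ok],
                        smiles = smiles_in[!ok], stringsAsFactors = FALSE)
  if (!any(ok)) stop("input error: zero parseable SMILES rows")
  lib <- data.frame(id = ids[ok], smiles = can[ok],
                    input_smiles = smiles_in[ok],
                    vendor = if (is.null(vendor)) NA_character_ else vendor[ok],
                    stringsAsFactors = FALSE)
  lib$n_components <- lengths(strsplit(lib$smiles, ".", fixed = TRUE))
  lib$duplicate <- duplicated(lib$smiles)
  if (encode_selfies) {
    toks <- to_selfies(lib$smiles)
    lib$selfies <- toks
    lib$selfies_ok <- !vapply(toks, is.null, TRUE)
  } else {
    lib$selfies <- vector("list", nrow(lib))
    lib$selfies_ok <- NA
  }
  structure(lib, rejects = rejects, tested_ids = character(0),
            class = c("candidate_library", "data.frame"))
}

#' @export
print.candidate_library <- function(x, ...) {
  rej <- attr(x, "rejects")
  cat("<candidate_library> ", nrow(x), " molecules (",
      sum(x$duplicate), " duplicate, ",
      if (all(is.na(x$selfies_ok))) "selfies not encoded" else
        paste0(sum(!x$selfies_ok), " selfies-failed"),
      "), ", nrow(rej), " rejected rows\n", sep = "")
  invisible(x)
}

#' Tested / untested partition of a library
#'
#' @param lib a `candidate_library`.
#' @param tested_ids character vector of molecule ids with measurements.
#' @return the library with its `tested_ids` attribute replaced; ids not in
#'   the library are an error.
#' @export
set_tested <- function(lib, tested_ids) {
  if (!all(tested_ids %in% lib$id)) stop("tested ids not in library")
  attr(lib, "tested_ids") <- unique(tested_ids)
  lib
}

#' @rdname set_tested
#' @export
untested_ids <- function(lib) setdiff(lib$id, attr(lib, "tested_ids"))

#' @rdname set_tested
#' @export
tested_ids <- function(lib) attr(lib, "tested_ids")

# ---------------------------------------------------------------------------
# fingerprints and similarity

#' ECFP4 (Morgan radius-2) fingerprints
#'
#' Multi-component molecules are fingerprinted as the single combined entity.
#'
#' @param smiles character vector of SMILES.
#' @param n_bits fingerprint length (default 2048).
#' @return a 0/1 integer matrix, one row per molecule; rows for unparseable
#'   molecules are `NA`.
#' @export
ecfp4_fingerprint <- function(smiles, n_bits = 2048L) {
  onbits <- ecfp_onbits(smiles, n_bits = n_bits)
  m <- matrix(0L, nrow = length(smiles), ncol = n_bits)
  for (i in seq_along(onbits)) {
    if (is.null(onbits[[i]])) m[i, ] <- NA_integer_ else m[i, onbits[[i]]] <- 1L
  }
  rownames(m) <- names(smiles)
  m
}

#' Tanimoto similarity between two bit vectors
#'
#' `|a AND b| / |a OR b|`.  Both-all-zero vectors are defined to have
#' similarity 1 (two "empty" structures are identical); this convention is
#' documented and tested.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("dimension error: fingerprint lengths differ")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

#' Maximum Tanimoto similarity of queries against a reference set
#'
#' For each query molecule, the most similar molecule in the reference set
#' (e.g. the bootstrap screen that trained the initial surrogates) and the
#' similarity value — the novelty analysis of discovered hits.
#'
#' @param query_smiles,reference_smiles character vectors of SMILES.
#' @param query_ids,reference_ids optional id vectors (defaults: the SMILES).
#' @param n_bits fingerprint length.
#' @return data.frame with columns `query_id`, `best_reference_id`,
#'   `similarity`.
#' @export
nearest_training_similarity <- function(query_smiles, reference_smiles,
                                        query_ids = query_smiles,
                                        reference_ids = reference_smiles,
                                        n_bits = 2048L) {
  if (length(reference_smiles) == 0L) stop("input error: empty reference set")
  if (length(query_smiles) == 0L) stop("input error: empty query set")
  fq <- ecfp4_fingerprint(query_smiles, n_bits)
  fr <- ecfp4_fingerprint(reference_smiles, n_bits)
  if (anyNA(fq) || anyNA(fr)) stop("unparseable molecule in similarity sets")
  inter <- fq %*% t(fr)
  pq <- rowSums(fq); pr <- rowSums(fr)
  uni <- outer(pq, pr, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  best <- apply(sim, 1, which.max)
  data.frame(query_id = query_ids,
             best_reference_id = reference_ids[best],
             similarity = sim[cbind(seq_along(best), best)],
             stringsAsFactors = FALSE)
}
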