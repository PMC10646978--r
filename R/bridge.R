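# Subprocess bridge to the RDKit cheminformatics backend.
#
# All chemistry primitives that require a real SMILES parser (canonicalization,
# kekulized molecular graphs, Morgan fingerprints, fr_* substructure counters)
# are delegated to RDKit through a batch JSON protocol: one python process per
# call, arbitrarily many molecules per call.  Callers must batch accordingly.

bridge_env <- new.env(parent = emptyenv())

bridge_script <- function() {
  p <- system.file("python", "chem_bridge.py", package = "immunoloop")
  if (!nzchar(p) || !file.exists(p)) {
    # during development (pkgload) fall back to the source tree
    p <- file.path("inst", "python", "chem_bridge.py")
  }
  if (!file.exists(p)) stop("chem_bridge.py not found")
  p
}

#' Call the RDKit backend
#'
#' Low-level batch call into the python/RDKit subprocess. Exposed mainly for
#' debugging; the typed wrappers below are the intended interface.
#'
#' @param op one of `"canonical"`, `"graph"`, `"ecfp"`, `"fragments"`.
#' @param smiles character vector of SMILES strings.
#' @param ... extra scalar fields for the request (e.g. `n_bits`).
#' @return the parsed JSON response as a list.
#' @keywords internal
bridge_call <- function(op, smiles, ...) {
  stopifnot(is.character(smiles))
  req <- c(list(op = op, smiles = as.list(smiles)), list(...))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(req, fin, auto_unbox = TRUE, null = "null")
  status <- system2("python", c(bridge_script(), fin, fout),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(fout)) {
    stop("RDKit bridge call failed (op=", op, ", status=", status, ")")
  }
  jsonlite::read_json(fout, simplifyVector = FALSE)
}

#' Canonicalize SMILES strings
#'
#' @param smiles character vector; unparseable entries map to `NA`.
#' @param strip_stereo drop stereochemistry flags before canonicalizing.
#'   The package works with a 2D topological representation throughout, so
#'   library ingestion canonicalizes with `strip_stereo = TRUE`.
#' @return character vector of RDKit canonical SMILES.
#' @export
canonical_smiles <- function(smiles, strip_stereo = FALSE) {
  if (length(smiles) == 0L) return(character(0))
  res <- bridge_call("canonical", smiles, strip_stereo = strip_stereo)
  vapply(res$canonical, function(x) if (is.null(x)) NA_character_ else x, "")
}

# Kekulized heavy-atom graphs: list per molecule with atoms (elem, charge, nH),
# bonds (a, b, order; 1-based indices), canonical SMILES and heavy-atom count.
# Unparseable molecules yield NULL.
molecular_graphs <- function(smiles) {
  if (length(smiles) == 0L) return(list())
  res <- bridge_call("graph", smiles)
  lapply(res$graphs, function(g) {
    if (is.null(g)) return(NULL)
    atoms <- data.frame(
      elem   = vapply(g$atoms, function(a) a[[1]], ""),
      charge = vapply(g$atoms, function(a) as.integer(a[[2]]), 0L),
      nH     = vapply(g$atoms, function(a) as.integer(a[[3]]), 0L),
      stringsAsFactors = FALSE)
    if (length(g$bonds)) {
      bonds <- data.frame(
        a = vapply(g$bonds, function(b) as.integer(b[[1]]) + 1L, 0L),
        b = vapply(g$bonds, function(b) as.integer(b[[2]]) + 1L, 0L),
        order = vapply(g$bonds, function(b) as.integer(b[[3]]), 0L))
    } else {
      bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0))
    }
    list(atoms = atoms, bonds = bonds, can = g$can, heavy = g$heavy)
  })
}

# ECFP4 on-bit indices (1-based) per molecule; NULL for unparseable.
ecfp_onbits <- function(smiles, n_bits = 2048L) {
  if (length(smiles) == 0L) return(list())
  res <- bridge_call("ecfp", smiles, n_bits = as.integer(n_bits))
  lapply(res$bits, function(b) {
    if (is.null(b)) return(NULL)
    vapply(b, as.integer, 0L) + 1L
  })
}

# Raw fr_* substructure counts; rows = molecules, cols = the 85 RDKit
# fragment counters in alphabetical order. Unparseable molecules get NA rows.
fragment_counts_raw <- function(smiles) {
  res <- bridge_call("fragments", smiles)
  names <- vapply(res$names, identity, "")
  m <- matrix(NA_integer_, nrow = length(smiles), ncol = length(names),
              dimnames = list(NULL, names))
  for (i in seq_along(res$counts)) {
    ci <- res$counts[[i]]
    if (!is.null(ci)) m[i, ] <- vapply(ci, as.integer, 0L)
  }
  m
}
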