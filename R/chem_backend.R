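#' @keywords internal
chemtool_path <- function() {
  path <- system.file("python", "chemtool.py", package = "screenlib")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is not yet installed
    path <- system.file("inst", "python", "chemtool.py", package = "screenlib")
  }
  if (!nzchar(path)) stop("bundled chemistry helper 'chemtool.py' not found")
  path
}

#' Is the RDKit chemistry backend available?
#'
#' The chemistry-backed functions ([standardize_compounds()],
#' [property_profile()], [chem_fingerprints()], [murcko_scaffolds()]) shell
#' out to a bundled Python helper that requires RDKit. This predicate checks
#' that `python` is on the PATH and can import RDKit.
#'
#' @return `TRUE` or `FALSE`.
#' @export
has_chem_backend <- function() {
  python <- Sys.which("python")
  if (!nzchar(python)) return(FALSE)
  status <- suppressWarnings(system2(python, c("-c", shQuote("import rdkit")),
                                     stdout = FALSE, stderr = FALSE))
  identical(status, 0L)
}

#' Run one chemtool command over a batch of structures
#'
#' @param command helper subcommand.
#' @param ids,smiles parallel character vectors.
#' @param args extra command-line arguments.
#' @return data.frame parsed from the helper's TSV output, in input order.
#' @keywords internal
run_chemtool <- function(command, ids, smiles, args = character()) {
  stopifnot(length(ids) == length(smiles))
  python <- Sys.which("python")
  if (!nzchar(python)) stop("no 'python' interpreter on the PATH")
  infile <- tempfile("chemtool-in-"); outfile <- tempfile("chemtool-out-")
  errfile <- tempfile("chemtool-err-")
  on.exit(unlink(c(infile, outfile, errfile)), add = TRUE)
  writeLines(paste(ids, smiles, sep = "\t"), infile)
  status <- system2(python, c(chemtool_path(), command, args),
                    stdin = infile, stdout = outfile, stderr = errfile)
  if (!identical(status, 0L)) {
    stop("chemistry helper failed (status ", status, "): ",
         paste(readLines(errfile, warn = FALSE), collapse = "; "))
  }
  out <- utils::read.delim(outfile, colClasses = "character", quote = "",
                           comment.char = "", na.strings = "NA",
                           check.names = FALSE)
  if (nrow(out) != length(ids)) {
    stop("chemistry helper returned ", nrow(out), " records for ",
         length(ids), " inputs")
  }
  out
}

#' Morgan fingerprints for a set of structures
#'
#' Computes hashed circular-substructure (Morgan) fingerprints, the 2D
#' descriptor used for both target prediction and Taylor-Butina clustering.
#'
#' @param smiles character vector of SMILES.
#' @param ids identifiers used as row names; defaults to `names(smiles)` or
#'   the SMILES themselves.
#' @param bits fingerprint length (default 2048).
#' @param radius circular substructure radius (default 2).
#' @return binary integer matrix, one row per input, `bits` columns.
#'   Unparseable structures raise an error.
#' @export
chem_fingerprints <- function(smiles, ids = NULL, bits = 2048L, radius = 2L) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else smiles
  out <- run_chemtool("fingerprint", ids, smiles,
                      c("--bits", bits, "--radius", radius))
  if (any(out$ok == "0")) {
    stop("unparseable SMILES for: ",
         paste(out$id[out$ok == "0"], collapse = ", "))
  }
  fp_from_bitstrings(out$fp_bits, bits = bits, ids = out$id)
}

#' @keywords internal
fp_from_bitstrings <- function(bitstrings, bits, ids) {
  mat <- matrix(0L, nrow = length(bitstrings), ncol = bits,
                dimnames = list(ids, NULL))
  for (i in seq_along(bitstrings)) {
    if (nzchar(bitstrings[i])) {
      on <- as.integer(strsplit(bitstrings[i], ",", fixed = TRUE)[[1]]) + 1L
      mat[i, on] <- 1L
    }
  }
  mat
}
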