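# Deterministic single-conformer embedding via RDKit's ETKDG algorithm,
# invoked through the system Python. One conformer per building block is
# enough for assembly; flexibility is probed later by the conformer search.

.python_bin <- function() {
  bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) stop("no `python` interpreter on PATH; ETKDG embedding needs RDKit")
  bin
}

#' Embed 3D conformers for SMILES
#'
#' Runs the ETKDG (v3) distance-geometry embedding with explicit hydrogens and
#' a fixed random seed, so identical inputs always give identical coordinates.
#'
#' @param smiles Character vector of SMILES.
#' @param seed Integer random seed passed to the embedding.
#' @param ids Optional identifiers used to label failures.
#' @return A named list, one entry per input: a `conformer` (list with
#'   `elements`, `coords` in Angstrom, `bonds` as an (i, j, order) matrix) or
#'   `NULL` where parsing/embedding failed.
#' @export
embed_smiles <- function(smiles, seed, ids = NULL) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (is.null(ids)) ids <- sprintf("mol%04d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  if (length(smiles) == 0L) return(structure(list(), names = character(0)))

  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste(smiles, ids, sep = "\t"), infile)

  script <- system.file("python", "embed_etkdg.py", package = "evocage")
  if (!nzchar(script)) stop("embed_etkdg.py not found in installed package")
  status <- system2(.python_bin(), c(shQuote(script), shQuote(infile),
                                     as.integer(seed), shQuote(outfile)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("ETKDG embedding subprocess failed (exit ", status, ")")

  out <- stats::setNames(vector("list", length(ids)), ids)
  if (!file.exists(outfile) || file.size(outfile) == 0L) return(out)
  sdf <- ChemmineR::read.SDFset(outfile)
  titles <- ChemmineR::sdfid(sdf)
  for (k in seq_along(titles)) {
    rec <- sdf[[k]]
    ab <- ChemmineR::atomblock(rec)
    bb <- ChemmineR::bondblock(rec)
    elements <- sub("_[0-9]+$", "", rownames(ab))
    bonds <- cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
    out[[titles[k]]] <- list(
      elements = elements,
      coords = unname(as.matrix(ab[, 1:3, drop = FALSE])),
      bonds = bonds
    )
  }
  out
}

#' @rdname embed_smiles
#' @param bb A `building_block`.
#' @export
embed_3d <- function(bb, seed) {
  stopifnot(inherits(bb, "building_block"))
  conf <- embed_smiles(bb$smiles, seed = seed, ids = bb$id)[[1]]
  if (is.null(conf)) stop("embedding failed for ", bb$id, " (", bb$smiles, ")")
  bb$conformer <- conf
  bb
}

# Pairwise distance of two coordinate rows.
.dist3 <- function(a, b) sqrt(sum((a - b)^2))

# All bonded distances of a conformer or structure.
bonded_distances <- function(x) {
  if (nrow(x$bonds) == 0L) return(numeric(0))
  sqrt(rowSums((x$coords[x$bonds[, 1], , drop = FALSE] -
                x$coords[x$bonds[, 2], , drop = FALSE])^2))
}
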