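#' Phased haplotype alignment for one locus
#'
#' The substrate of all locus-wise summary statistics: a character matrix of
#' aligned haplotype sequences over \code{{a,c,g,t,-,n}} plus per-row metadata
#' (individual, haplotype index, species, ploidy). A diploid contributes up to
#' two rows, a tetraploid up to four.
#'
#' @param seqs Character matrix (rows = haplotypes, columns = sites); case is
#'   normalised to lower.
#' @param meta Data frame with columns \code{individual}, \code{haplotype},
#'   \code{species}, \code{ploidy}; one row per sequence row.
#' @param locus_id Locus identifier.
#' @return An object of class \code{locus_alignment}.
#' @export
locus_alignment <- function(seqs, meta, locus_id = "L1") {
  if (!is.matrix(seqs) || !is.character(seqs))
    stop("seqs must be a character matrix")
  if (nrow(seqs) != nrow(meta))
    stop("meta must have one row per sequence")
  need <- c("individual", "haplotype", "species", "ploidy")
  if (!all(need %in% names(meta)))
    stop("meta must have columns: ", paste(need, collapse = ", "))
  np <- tapply(meta$haplotype, meta$individual, length)
  pl <- tapply(meta$ploidy, meta$individual, function(x) x[1L])
  bad <- names(np)[np > pl[names(np)]]
  if (length(bad))
    stop("more haplotypes than ploidy for: ", paste(bad, collapse = ", "))
  seqs[] <- tolower(seqs)
  rownames(seqs) <- paste0(meta$individual, "|h", meta$haplotype)
  structure(list(locus_id = locus_id, seqs = seqs, meta = meta),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d haplotypes x %d sites, %d species\n",
              x$locus_id, nrow(x$seqs), ncol(x$seqs),
              length(unique(x$meta$species))))
  invisible(x)
}

#' Write / read a locus alignment as FASTA
#'
#' Headers follow the convention \code{>INDIVIDUAL|hN|SPECIES|PLOIDY}.
#'
#' @param aln A \code{\link{locus_alignment}}.
#' @param path Output (input) FASTA file.
#' @export
write_locus_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "locus_alignment"))
  hdr <- sprintf(">%s|h%d|%s|%d", aln$meta$individual, aln$meta$haplotype,
                 aln$meta$species, aln$meta$ploidy)
  lines <- character(2L * nrow(aln$seqs))
  lines[c(TRUE, FALSE)] <- hdr
  lines[c(FALSE, TRUE)] <- apply(aln$seqs, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_locus_fasta
#' @param locus_id Locus id for the object read back (defaults to file name).
#' @export
read_locus_fasta <- function(path, locus_id = NULL) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(as.character(as.matrix(dna)))
  seqs[] <- tolower(seqs)
  parts <- strsplit(names(dna), "|", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("FASTA headers must follow INDIVIDUAL|hN|SPECIES|PLOIDY")
  meta <- data.frame(
    individual = vapply(parts, `[`, "", 1L),
    haplotype = as.integer(sub("^h", "", vapply(parts, `[`, "", 2L))),
    species = vapply(parts, `[`, "", 3L),
    ploidy = as.integer(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  if (is.null(locus_id))
    locus_id <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  locus_alignment(unname(seqs), meta, locus_id = locus_id)
}

#' Read / write site allele-count tables
#'
#' Tab-separated with header, columns \code{individual species locus site
#' countA countB countOther} (\code{site} 0-based). Optional columns
#' \code{alleleA}/\code{alleleB} carry allele identities used when combining
#' individuals.
#'
#' @param path TSV file path.
#' @return A data frame of per-site allele counts.
#' @export
read_counts_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "species", "locus", "site", "countA", "countB",
            "countOther")
  if (!all(need %in% names(x)))
    stop("counts TSV must have columns: ", paste(need, collapse = " "))
  if (any(x$countA < 0 | x$countB < 0 | x$countOther < 0))
    stop("negative read counts")
  key <- paste(x$individual, x$locus, x$site)
  if (anyDuplicated(key))
    stop("site index must be unique within (individual, locus)")
  x
}

#' @rdname read_counts_tsv
#' @param counts Data frame of counts.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- suitability rasters -------------------------------------------------

#' Gridded presence-probability raster
#'
#' Minimal in-memory raster: a numeric matrix of presence probabilities in
#' \code{[0, 1]} (or \code{NA} for nodata) with lower-left-corner
#' georeferencing, as produced by thresholdable species-distribution-model
#' output on the cloglog (0-1 probability) scale.
#'
#' @param values Numeric matrix of probabilities; \code{NA} = nodata.
#' @param xll,yll Coordinates of the lower-left corner.
#' @param cellsize Cell size (square cells).
#' @param crs Free-text CRS tag.
#' @return An object of class \code{suit_raster}.
#' @export
suit_raster <- function(values, xll = 0, yll = 0, cellsize = 1,
                        crs = "EPSG:4326") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (!all(is.na(values))) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("probabilities must lie in [0, 1]")
  }
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize,
                 crs = crs),
            class = "suit_raster")
}

#' @export
print.suit_raster <- function(x, ...) {
  cat(sprintf("<suit_raster> %d x %d cells, cellsize %g, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format: a six-line header (\code{ncols},
#' \code{nrows}, \code{xllcorner}, \code{yllcorner}, \code{cellsize},
#' \code{NODATA_value}) followed by rows of cell values, top row first.
#'
#' @param r A \code{\link{suit_raster}}.
#' @param path File path.
#' @param nodata Sentinel written for \code{NA} cells.
#' @export
write_esri_ascii <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "suit_raster"))
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", r$xll), paste("yllcorner", r$yll),
           paste("cellsize", r$cellsize), paste("NODATA_value", nodata))
  body <- apply(v, 1L, function(row)
    paste(format(row, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]]); nrows <- as.integer(vals[["nrows"]])
  nodata <- vals[["nodata_value"]]
  cells <- scan(text = paste(lines[-(1:6)], collapse = " "), quiet = TRUE)
  if (length(cells) != ncols * nrows)
    stop("cell count does not match header dimensions")
  m <- matrix(cells, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  suit_raster(m, xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
              cellsize = vals[["cellsize"]])
}
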