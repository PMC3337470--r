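#' Read an ms-style haplotype replicate
#'
#' Parses the text dialect emitted by ms-family coalescent simulators: a
#' `segsites:` line, a `positions:` line of fractions in \[0, 1\], then one
#' 0/1 string per haplotype.  Lines before `segsites:` (command echo,
#' seeds, `//`) are ignored.  Fractional positions are scaled to base
#' pairs (`round(fraction * physical_length)`, minimum 1); ties after
#' rounding are resolved by bumping a colliding site to the next free
#' coordinate.
#'
#' @param con a file path or connection, or a character vector of lines.
#' @param chrom a [chromosome_spec()] giving the physical length.
#' @return a `haplotype_panel`.
#' @export
read_ms_panel <- function(con, chrom) {
  stopifnot(inherits(chrom, "chromosome_spec"))
  lines <- if (is.character(con) && length(con) > 1) con
           else if (is.character(con) && !file.exists(con)) strsplit(con, "\n")[[1]]
           else readLines(con)
  seg_i <- grep("^segsites:", lines)
  if (length(seg_i) == 0)
    stop("no 'segsites:' line found in ms input")
  seg_i <- seg_i[1]
  S <- suppressWarnings(as.integer(sub("^segsites:\\s*", "", lines[seg_i])))
  if (is.na(S) || S < 0)
    stop("line ", seg_i, ": malformed segsites count")
  if (S == 0)
    return(new_haplotype_panel(chrom, numeric(0), matrix(0L, 0, 0)))

  pos_i <- seg_i + 1L
  if (pos_i > length(lines) || !grepl("^positions:", lines[pos_i]))
    stop("line ", pos_i, ": expected 'positions:' line")
  fr <- suppressWarnings(as.numeric(
    strsplit(trimws(sub("^positions:\\s*", "", lines[pos_i])), "\\s+")[[1]]))
  if (anyNA(fr) || length(fr) != S)
    stop("line ", pos_i, ": expected ", S, " numeric positions")
  if (any(fr < 0 | fr > 1))
    stop("line ", pos_i, ": positions must be fractions in [0, 1]")

  rest_idx <- seq(pos_i + 1L, length.out = max(0L, length(lines) - pos_i))
  hap_idx <- rest_idx[nzchar(trimws(lines[rest_idx]))]
  if (length(hap_idx) == 0) stop("no haplotype lines found")
  alleles <- matrix(0L, nrow = length(hap_idx), ncol = S)
  for (i in seq_along(hap_idx)) {
    lineno <- hap_idx[i]
    ln <- trimws(lines[lineno])
    if (nchar(ln) != S)
      stop("line ", lineno, ": haplotype has ", nchar(ln),
           " characters, expected ", S)
    ch <- strsplit(ln, "", fixed = TRUE)[[1]]
    if (any(!ch %in% c("0", "1")))
      stop("line ", lineno, ": non-binary character in haplotype")
    alleles[i, ] <- as.integer(ch)
  }

  bp <- pmax(1, round(fr * chrom$physical_length_bp))
  for (j in seq_along(bp)[-1]) {
    if (bp[j] <= bp[j - 1]) bp[j] <- bp[j - 1] + 1
  }
  if (length(bp) && bp[length(bp)] > chrom$physical_length_bp)
    stop("positions overflow the chromosome after tie resolution")
  new_haplotype_panel(chrom, bp, alleles)
}

#' Write a haplotype panel in the ms dialect
#'
#' Inverse of [read_ms_panel()]: positions are written as fractions of the
#' physical length at full double precision, so a write/read round trip
#' restores positions and the allele matrix exactly.
#'
#' @param panel a `haplotype_panel`.
#' @param con a file path or connection; omit to return the lines.
#' @return invisibly, the character vector of lines written.
#' @export
write_ms_panel <- function(panel, con = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  S <- length(panel$positions)
  lines <- c("//", paste0("segsites: ", S))
  if (S > 0) {
    fr <- sprintf("%.17g", panel$positions / panel$chromosome$physical_length_bp)
    lines <- c(lines,
               paste("positions:", paste(fr, collapse = " ")),
               apply(panel$alleles, 1, paste, collapse = ""))
  }
  if (!is.null(con)) writeLines(lines, con)
  invisible(lines)
}
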