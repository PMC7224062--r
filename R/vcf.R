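#' Write calls to a VCF 4.3 file
#'
#' Minimal single-sample VCF with the pipeline's INFO schema: depth (DP),
#' allelic depths (AD), variant allele fraction (VAF), quality-control
#' flags (QCFLAGS) and the mosaic-scan binomial p value (MOSAIC_P).
#'
#' @param calls A `pkd_calls` tibble.
#' @param path Output path.
#' @param contig Contig name written in CHROM and the header.
#' @param contig_length Contig length for the header, if known.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, path, contig = "GENE",
                              contig_length = NA_integer_) {
  header <- c(
    "##fileformat=VCFv4.3",
    "##source=pkdpanel",
    if (!is.na(contig_length)) {
      paste0("##contig=<ID=", contig, ",length=", contig_length, ">")
    } else paste0("##contig=<ID=", contig, ">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=QCFLAGS,Number=.,Type=String,Description=\"Advisory QC flags\">",
    "##INFO=<ID=MOSAIC_P,Number=1,Type=Float,Description=\"Binomial tail p value from the mosaic scan\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) == 0) {
    readr::write_lines(header, path)
    return(invisible(path))
  }
  flags <- vapply(calls$qc_flags, function(f) {
    if (length(f) == 0) "" else paste0(";QCFLAGS=", paste(f, collapse = ","))
  }, character(1))
  mos <- ifelse(is.na(calls$mosaic_p), "",
                sprintf(";MOSAIC_P=%.3g", calls$mosaic_p))
  info <- sprintf("DP=%d;AD=%d,%d;VAF=%.4f%s%s",
                  calls$depth, calls$depth - calls$alt_depth,
                  calls$alt_depth, calls$vaf, flags, mos)
  body <- paste(contig, calls$pos, ".", calls$ref, calls$alt, ".",
                "PASS", info, sep = "\t")
  readr::write_lines(c(header, body), path)
  invisible(path)
}
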