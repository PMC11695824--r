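#' Hotspot mutation panel
#'
#' A hotspot panel is the catalog of recurrent somatic point mutations the
#' assay targets: one row per site with gene symbol, 1-based genomic
#' coordinate (VCF convention), reference and alternate allele, a protein
#' change label and an actionability flag.
#'
#' @param sites data.frame with columns `site_id`, `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `protein_change`, `actionable`.
#' @return A `hotspot_panel`: a validated data.frame.
#' @export
hotspot_panel <- function(sites) {
  check_columns(sites, c("site_id", "gene", "chrom", "pos", "ref", "alt",
                         "protein_change", "actionable"), "panel")
  sites$site_id <- as.character(sites$site_id)
  sites$gene <- as.character(sites$gene)
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  sites$protein_change <- as.character(sites$protein_change)
  sites$actionable <- as.logical(as.integer(sites$actionable))
  dup <- sites$site_id[duplicated(sites$site_id)]
  if (length(dup))
    stopf("panel has duplicate site_id(s): %s",
          paste(unique(dup), collapse = ", "))
  key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (anyDuplicated(key))
    stopf("panel has duplicate (chrom,pos,ref,alt) locus: %s",
          key[duplicated(key)][1])
  if (any(sites$ref == sites$alt))
    stopf("panel row %s has ref == alt",
          sites$site_id[sites$ref == sites$alt][1])
  if (any(sites$pos < 1L)) stopf("panel positions must be >= 1 (1-based)")
  rownames(sites) <- NULL
  class(sites) <- c("hotspot_panel", "data.frame")
  sites
}

#' Read a hotspot panel from TSV or VCF
#'
#' TSV must carry the full panel schema; VCF (4.2, plain text) must carry
#' `GENE`, `PCHANGE` and `ACTIONABLE` INFO keys as written by
#' [write_panel()].
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`; default guesses from the extension.
#' @return A [hotspot_panel()].
#' @export
read_panel <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    return(hotspot_panel(df))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  info1 <- function(key) {
    m <- regmatches(fix$INFO,
                    regexpr(paste0("(^|;)", key, "=[^;]*"), fix$INFO))
    sub(paste0("^;?", key, "="), "", m)
  }
  hotspot_panel(data.frame(
    site_id = fix$ID, gene = info1("GENE"), chrom = fix$CHROM,
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    protein_change = info1("PCHANGE"),
    actionable = as.integer(info1("ACTIONABLE")),
    stringsAsFactors = FALSE))
}

#' Write a hotspot panel as TSV or VCF 4.2
#'
#' @param panel a [hotspot_panel()].
#' @param path output file path.
#' @param format `"tsv"` (full schema) or `"vcf"` (sites with gene and
#'   protein change as INFO keys).
#' @export
write_panel <- function(panel, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  panel <- hotspot_panel(as.data.frame(panel))
  if (format == "tsv") {
    out <- panel
    out$actionable <- as.integer(out$actionable)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
    paste0("##INFO=<ID=ACTIONABLE,Number=1,Type=Integer,",
           "Description=\"1 if linked to an approved targeted therapy\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tGENE=%s;PCHANGE=%s;ACTIONABLE=%d",
                  panel$chrom, panel$pos, panel$site_id, panel$ref, panel$alt,
                  panel$gene, panel$protein_change,
                  as.integer(panel$actionable))
  writeLines(c(hdr, body), path)
  invisible(path)
}
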