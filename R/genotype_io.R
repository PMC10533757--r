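#' Read a genotype matrix from VCF or dosage CSV
#'
#' VCF records are read GT-only through \pkg{vcfR}; multi-allelic records
#' are skipped (their count is reported in a message). The dosage CSV
#' dialect has a header row of SNP ids, one row per individual with the id
#' in the first column, and cells in {0,1,2,NA}; chromosome/position are
#' recovered from SNP ids of the form `chr<k>_<pos>` when present,
#' otherwise all SNPs are placed on one pseudo-chromosome at their column
#' index.
#'
#' @param path file path.
#' @param format `"vcf"` or `"dosage_csv"`; guessed from the extension when
#'   missing.
#' @return A [marker_matrix()].
#' @export
read_genotypes <- function(path, format = c("guess", "vcf", "dosage_csv")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_csv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    message(sum(multi), " multi-allelic record(s) skipped")
  keep <- which(!multi)
  if (length(keep) == 0) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  dos <- apply(gt, 2, function(col) {
    col <- gsub("\\|", "/", col)
    out <- rep(NA_real_, length(col))
    out[col %in% c("0/0")] <- 0
    out[col %in% c("0/1", "1/0")] <- 1
    out[col %in% c("1/1")] <- 2
    out
  })
  dos <- matrix(dos, ncol = ncol(gt), dimnames = dimnames(gt))
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])[noid]
  d <- t(dos)
  colnames(d) <- ids
  marker_matrix(d, fix[keep, "CHROM"], as.integer(fix[keep, "POS"]))
}

read_genotypes_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  ids <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  rownames(d) <- ids
  nm <- colnames(d)
  hit <- regmatches(nm, regexec("^(chr[0-9A-Za-z]+)_([0-9]+)$", nm))
  ok <- lengths(hit) == 3
  if (all(ok)) {
    chrom <- vapply(hit, `[`, "", 2)
    pos <- as.integer(vapply(hit, `[`, "", 3))
  } else {
    chrom <- rep("chr0", ncol(d))
    pos <- seq_len(ncol(d))
  }
  marker_matrix(d, chrom, pos)
}

#' Write genotypes as an uncompressed VCF 4.2 file
#'
#' One sample per individual, GT field only, contigs taken from the map.
#' Integer dosages map to `0/0`, `0/1`, `1/1`; fractional (imputed) dosages
#' cannot be represented and raise an error; missing becomes `./.`.
#'
#' @param m a [marker_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(m, path) {
  d <- m$dosage
  if (any(!is.na(d) & d != round(d)))
    stop("fractional dosages cannot be written as GT calls")
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  codes <- c("0/0", "0/1", "1/1")
  obs <- !is.na(t(d))
  gt[obs] <- codes[t(d)[obs] + 1]
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(m$map$chromosome), ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- paste(m$map$chromosome, m$map$position, m$map$snp_id, "A", "T",
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write genotypes as a dosage CSV
#'
#' Header row of SNP ids (`chr<k>_<pos>` form so the map round-trips), one
#' row per individual, first column the individual id.
#'
#' @inheritParams write_genotypes_vcf
#' @export
write_dosage_csv <- function(m, path) {
  d <- m$dosage
  colnames(d) <- paste0(m$map$chromosome, "_", m$map$position)
  out <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
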