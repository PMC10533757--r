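#' Marker matrix container
#'
#' Holds a biallelic SNP dosage matrix (individuals x markers, values 0/1/2
#' or `NA`) together with its chromosome/position map. Dosage counts copies
#' of the alternate allele.
#'
#' @param dosage numeric matrix, individuals in rows, SNPs in columns.
#'   Row names are individual ids, column names SNP ids.
#' @param chromosome character vector, one chromosome label per SNP.
#' @param position integer vector, 1-based bp position per SNP; positions
#'   must be strictly increasing within a chromosome.
#' @return An object of class `marker_matrix` with elements `dosage` and
#'   `map` (data.frame: `snp_id`, `chromosome`, `position`).
#' @export
marker_matrix <- function(dosage, chromosome, position) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  if (length(chromosome) != ncol(dosage) || length(position) != ncol(dosage))
    stop("chromosome/position must have one entry per SNP column")
  # raw calls are 0/1/2; mean-imputed cells may be fractional but stay in range
  bad <- !is.na(dosage) & (dosage < 0 | dosage > 2)
  if (any(bad))
    stop("dosage values must lie in [0, 2] or be NA")
  map <- data.frame(snp_id = colnames(dosage),
                    chromosome = as.character(chromosome),
                    position = as.integer(position),
                    stringsAsFactors = FALSE)
  # enforce sorted positions within chromosome
  ord <- order(factor(map$chromosome, levels = unique(map$chromosome)),
               map$position)
  map <- map[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  for (ch in unique(map$chromosome)) {
    p <- map$position[map$chromosome == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  rownames(map) <- NULL
  structure(list(dosage = dosage, map = map), class = "marker_matrix")
}

#' @export
#' @method print marker_matrix
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs on",
      length(unique(x$map$chromosome)), "chromosome(s);",
      sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$dosage)

ind_ids <- function(m) rownames(m$dosage)
snp_ids <- function(m) colnames(m$dosage)

#' Subset a marker matrix
#'
#' @param m a [marker_matrix()].
#' @param individuals,snps character ids or index vectors; `NULL` keeps all.
#' @return A `marker_matrix` restricted to the requested rows/columns.
#' @export
subset_markers <- function(m, individuals = NULL, snps = NULL) {
  d <- m$dosage
  if (!is.null(individuals)) d <- d[individuals, , drop = FALSE]
  if (!is.null(snps)) d <- d[, snps, drop = FALSE]
  keep <- match(colnames(d), m$map$snp_id)
  marker_matrix(d, m$map$chromosome[keep], m$map$position[keep])
}
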