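#' Write a GenotypeDataset as minimal VCF 4.2 plus metadata CSVs
#'
#' Emits a plain-text VCF with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT
#' columns and a single GT field per sample (all loci on pseudo-chromosome
#' "1", positions = locus index, REF = A, ALT = C), together with a site
#' metadata CSV and an individual-to-site mapping CSV next to it.
#'
#' @param x a [GenotypeDataset-class].
#' @param path output VCF path; `<path>.sites.csv` and
#'   `<path>.individuals.csv` are written alongside.
#' @return `path`, invisibly.
#' @export
writeVCF <- function(x, path) {
  g <- dosages(x)
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  gt[is.na(g)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=seascapeConn",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(g)), collapse = "\t")
  )
  body <- paste(
    "1", seq_len(nrow(g)), rownames(g), "A", "C", ".", ".", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t")
  writeLines(c(header, body), path)
  write.csv(siteTable(x), paste0(path, ".sites.csv"), row.names = FALSE)
  write.csv(data.frame(sample_id = colnames(g), site_id = siteOf(x)),
            paste0(path, ".individuals.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a minimal biallelic VCF into a GenotypeDataset
#'
#' Parses the file with `vcfR`, keeps the GT field as an alt-allele dosage
#' (0/1/2, `./.` as `NA`), and attaches site metadata. Records that are not
#' biallelic SNPs are rejected with an error listing their ids.
#'
#' @param path VCF path (plain text or gzipped).
#' @param sites site metadata data.frame; defaults to `<path>.sites.csv`.
#' @param individuals data.frame with `sample_id`, `site_id`; defaults to
#'   `<path>.individuals.csv`. Every VCF sample must be listed.
#' @return A [GenotypeDataset-class].
#' @export
readVCF <- function(path, sites = NULL, individuals = NULL) {
  if (is.null(sites)) sites <- read.csv(paste0(path, ".sites.csv"))
  if (is.null(individuals)) {
    individuals <- read.csv(paste0(path, ".individuals.csv"))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  bad <- is.na(alt) | alt == "." | grepl(",", alt) |
    nchar(alt) != 1L | nchar(ref) != 1L
  if (any(bad)) {
    stop("non-biallelic SNP record(s): ",
         paste(fix[bad, "ID"], collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  unknown <- !is.na(gt) & is.na(dos) & clean != "./."
  if (any(unknown)) stop("unparseable GT values, e.g. ", gt[which(unknown)[1]])
  samp <- colnames(dos)
  hit <- match(samp, individuals$sample_id)
  if (anyNA(hit)) {
    stop("missing site metadata for sample(s): ",
         paste(samp[is.na(hit)], collapse = ", "))
  }
  rownames(dos) <- fix[, "ID"]
  genotypeDataset(dos, individuals$site_id[hit], sites,
                  individualIds = samp, lociIds = fix[, "ID"])
}
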