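#' Construct a cohort object
#'
#' The canonical in-memory representation of a case-control genotype study:
#' a SNP panel table, a sample/phenotype table, and a dosage matrix counting
#' copies of a per-SNP "counted" allele (0/1/2, `NA` = missing call).
#'
#' @param snps data.frame with columns `snp_id`, `chromosome`, `position`,
#'   `allele_a`, `allele_b`, `gene`. Positions are 1-based; `gene` may be "".
#' @param samples data.frame with columns `sample_id`, `status`
#'   (1 = case, 0 = control), `sex` (0/1), `age` (years).
#' @param geno integer matrix, `nrow(samples)` x `nrow(snps)`, entries in
#'   \{0, 1, 2, NA\}; rows named by sample id, columns by SNP id.
#' @param counted_allele character vector, one base per SNP: the allele whose
#'   copies `geno` counts. Defaults to `snps$allele_a`.
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(snps, samples, geno, counted_allele = snps$allele_a) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_snp <- c("snp_id", "chromosome", "position", "allele_a", "allele_b", "gene")
  if (!all(need_snp %in% names(snps)))
    stop("snps must have columns: ", paste(need_snp, collapse = ", "))
  need_smp <- c("sample_id", "status", "sex", "age")
  if (!all(need_smp %in% names(samples)))
    stop("samples must have columns: ", paste(need_smp, collapse = ", "))
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id in panel")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (!all(samples$status %in% c(0L, 1L))) stop("status must be 0/1")
  if (any(!is.na(snps$position) & snps$position <= 0)) stop("positions must be > 0")
  if (any(snps$allele_a == snps$allele_b)) stop("allele_a must differ from allele_b")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(samples) || ncol(geno) != nrow(snps))
    stop("geno dimensions do not match samples x snps")
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2)) stop("genotype dosages must be 0, 1, 2 or NA")
  rownames(geno) <- samples$sample_id
  colnames(geno) <- snps$snp_id
  if (length(counted_allele) != nrow(snps))
    stop("counted_allele must have one entry per SNP")
  structure(
    list(snps = snps, samples = samples, geno = geno,
         counted_allele = as.character(counted_allele)),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples (%d cases / %d controls), %d SNPs on %d chromosome(s)\n",
              nrow(x$samples), sum(x$samples$status == 1),
              sum(x$samples$status == 0), nrow(x$snps),
              length(unique(x$snps$chromosome))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  call rate %.4f; counted alleles: %s...\n",
              1 - miss, paste(head(x$counted_allele, 5), collapse = ",")))
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$geno)

#' Subset a cohort by SNPs and/or samples
#'
#' @param cohort a [new_cohort()] object.
#' @param snps SNP ids or column indices to keep (default all).
#' @param samples sample ids or row indices to keep (default all).
#' @return A `cohort` with the requested subset, order preserved as given.
#' @export
subset_cohort <- function(cohort, snps = NULL, samples = NULL) {
  j <- seq_len(nrow(cohort$snps))
  if (!is.null(snps)) {
    j <- if (is.character(snps)) match(snps, cohort$snps$snp_id) else as.integer(snps)
    if (anyNA(j)) stop("unknown snp id(s): ",
                       paste(snps[is.na(j)], collapse = ", "))
  }
  i <- seq_len(nrow(cohort$samples))
  if (!is.null(samples)) {
    i <- if (is.character(samples)) match(samples, cohort$samples$sample_id)
         else as.integer(samples)
    if (anyNA(i)) stop("unknown sample id(s)")
  }
  new_cohort(cohort$snps[j, , drop = FALSE],
             cohort$samples[i, , drop = FALSE],
             cohort$geno[i, j, drop = FALSE],
             cohort$counted_allele[j])
}

.valid_bases <- c("A", "C", "G", "T")

#' Read PLINK-style text PED/MAP files
#'
#' PED: whitespace-delimited, 6 mandatory columns (family id, individual id,
#' paternal id, maternal id, sex 1=male/2=female, phenotype 1=control/2=case)
#' then two allele columns per SNP ("0 0" = missing). MAP: chromosome, snp id,
#' genetic distance, base-pair position. An optional covariate TSV supplies
#' age (PED carries none); otherwise age is `NA`.
#'
#' After reading, dosages count the whole-sample minor allele
#' (see [recode_to_minor()]).
#'
#' @param ped_path,map_path file paths.
#' @param covar_path optional TSV with columns `sample_id`, `age`.
#' @return A [new_cohort()] object.
#' @export
read_plink_text <- function(ped_path, map_path, covar_path = NULL) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_tok)
  if (any(nf != 4))
    stop("MAP parse error at line ", which(nf != 4)[1],
         ": expected 4 columns, found ", nf[nf != 4][1])
  map <- do.call(rbind, map_tok)
  snps <- data.frame(
    snp_id = map[, 2], chromosome = map[, 1],
    position = as.integer(map[, 4]),
    allele_a = NA_character_, allele_b = NA_character_,
    gene = "", stringsAsFactors = FALSE)
  m <- nrow(snps)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_tok <- strsplit(trimws(ped_lines), "[ \t]+")
  nf <- lengths(ped_tok)
  expected <- 6 + 2 * m
  if (any(nf != expected))
    stop("PED parse error at line ", which(nf != expected)[1],
         ": expected ", expected, " columns, found ", nf[nf != expected][1])
  n <- length(ped_tok)
  ped <- matrix(unlist(ped_tok), nrow = n, byrow = TRUE)

  pheno <- ped[, 6]
  if (!all(pheno %in% c("1", "2")))
    stop("PED phenotype must be 1 (control) or 2 (case)")
  sex_raw <- ped[, 5]
  samples <- data.frame(
    sample_id = ped[, 2],
    status = as.integer(pheno == "2"),
    sex = ifelse(sex_raw %in% c("1", "2"), as.integer(sex_raw) - 1L, NA_integer_),
    age = NA_integer_, stringsAsFactors = FALSE)

  allele_tokens <- ped[, -(1:6), drop = FALSE]
  bad <- matrix(!(allele_tokens %in% c(.valid_bases, "0")),
                nrow(allele_tokens))
  if (any(bad)) {
    ln <- which(apply(bad, 1, any))[1]
    stop("PED parse error at line ", ln, ": non-ACGT0 allele token '",
         allele_tokens[bad][1], "'")
  }

  geno <- matrix(NA_integer_, n, m)
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    a1 <- allele_tokens[, 2 * j - 1]
    a2 <- allele_tokens[, 2 * j]
    if (xor(a1 == "0", a2 == "0")[1] || any(xor(a1 == "0", a2 == "0")))
      stop("PED: half-missing genotype at SNP ", snps$snp_id[j])
    obs <- sort(unique(c(a1, a2)))
    obs <- setdiff(obs, "0")
    if (length(obs) > 2)
      stop("SNP ", snps$snp_id[j], " has >2 alleles in PED")
    if (length(obs) == 0) obs <- c("A", "C")        # all-missing column
    if (length(obs) == 1) obs <- c(obs, setdiff(.valid_bases, obs)[1])
    allele_a[j] <- obs[1]; allele_b[j] <- obs[2]
    d <- (a1 == obs[1]) + (a2 == obs[1])
    d[a1 == "0"] <- NA_integer_
    geno[, j] <- as.integer(d)
  }
  snps$allele_a <- allele_a
  snps$allele_b <- allele_b

  if (!is.null(covar_path)) {
    cov <- read.table(covar_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    idx <- match(samples$sample_id, cov$sample_id)
    samples$age <- as.integer(cov$age[idx])
  }
  recode_to_minor(new_cohort(snps, samples, geno, counted_allele = allele_a))
}

#' Write a cohort as PLINK-style text PED/MAP
#'
#' @param cohort a [new_cohort()] object.
#' @param ped_path,map_path output paths.
#' @param covar_path optional TSV path for the age covariate (PED itself
#'   carries no age); readable back via `read_plink_text(covar_path =)`.
#' @return Invisibly, the paths.
#' @export
write_plink_text <- function(cohort, ped_path, map_path, covar_path = NULL) {
  snps <- cohort$snps
  map <- paste(snps$chromosome, snps$snp_id, 0, snps$position)
  writeLines(map, map_path)

  n <- nrow(cohort$samples); m <- nrow(snps)
  counted <- cohort$counted_allele
  other <- ifelse(counted == snps$allele_a, snps$allele_b, snps$allele_a)
  al <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    d <- cohort$geno[, j]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, counted[j], other[j]))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, counted[j], other[j]))
    al[, 2 * j - 1] <- a1; al[, 2 * j] <- a2
  }
  smp <- cohort$samples
  lead <- cbind(smp$sample_id, smp$sample_id, "0", "0",
                ifelse(is.na(smp$sex), "0", as.character(smp$sex + 1L)),
                as.character(smp$status + 1L))
  writeLines(apply(cbind(lead, al), 1, paste, collapse = " "), ped_path)
  if (!is.null(covar_path)) {
    write.table(smp[, c("sample_id", "age")], covar_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(c(ped = ped_path, map = map_path, covar = covar_path)))
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a VCF (GT field) plus a phenotype table
#'
#' Biallelic SNPs only; phased and unphased separators are both accepted and
#' phase is discarded (all downstream methods assume unphased data). "./." is
#' missing. A `GENE=` INFO key, when present, fills the gene annotation.
#'
#' @param vcf_path VCF v4.x path (uncompressed or bgzipped).
#' @param pheno_path TSV with header `sample_id`, `status`, `sex`, `age`.
#' @param normalize_chrom strip a leading "chr" from chromosome labels.
#' @return A [new_cohort()] object with dosages counting the minor allele.
#' @export
read_vcf <- function(vcf_path, pheno_path, normalize_chrom = FALSE) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fixmat <- vcfR::getFIX(v)
  if (is.null(dim(fixmat))) fixmat <- t(fixmat)   # single-variant VCF
  fix <- as.data.frame(fixmat, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
  if (any(multi))
    stop("multi-allelic or non-SNP record at position(s): ",
         paste(fix$POS[multi], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))

  pheno <- read.table(pheno_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
  vcf_samples <- colnames(gt)
  missing_pheno <- setdiff(vcf_samples, pheno$sample_id)
  if (length(missing_pheno))
    stop("samples in VCF but not in phenotype table: ",
         paste(missing_pheno, collapse = ", "))
  pheno <- pheno[match(vcf_samples, pheno$sample_id), , drop = FALSE]

  gt_clean <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt_clean == "0/0"] <- 0L
  dos[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos[gt_clean == "1/1"] <- 2L
  unknown <- !is.na(gt_clean) & !(gt_clean %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(unknown)) stop("unsupported GT value: ", gt_clean[unknown][1])

  info <- vcfR::getINFO(v)
  gene <- rep("", nrow(fix))
  has_gene <- !is.na(info) & grepl("(^|;)GENE=", info)
  gene[has_gene] <- sub(".*GENE=", "",
                        regmatches(info[has_gene],
                                   regexpr("(^|;)GENE=[^;]*", info[has_gene])))

  chrom <- fix$CHROM
  if (normalize_chrom) chrom <- sub("^chr", "", chrom)
  snps <- data.frame(
    snp_id = fix$ID, chromosome = chrom, position = as.integer(fix$POS),
    allele_a = fix$REF, allele_b = fix$ALT, gene = gene,
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = vcf_samples,
    status = as.integer(pheno$status),
    sex = as.integer(pheno$sex),
    age = as.integer(pheno$age), stringsAsFactors = FALSE)
  # GT counts ALT copies: counted allele starts as ALT (= allele_b)
  recode_to_minor(new_cohort(snps, samples, t(dos),
                             counted_allele = snps$allele_b))
}

#' Write a cohort as VCF v4.2 plus a phenotype TSV
#'
#' GT is emitted unphased with REF = the non-counted allele and ALT = the
#' counted allele; gene labels are carried in `GENE=` INFO entries so a VCF
#' round trip is the identity on the panel annotation.
#'
#' @param cohort a [new_cohort()] object.
#' @param vcf_path,pheno_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_vcf <- function(cohort, vcf_path, pheno_path) {
  snps <- cohort$snps
  counted <- cohort$counted_allele
  ref <- ifelse(counted == snps$allele_a, snps$allele_b, snps$allele_a)
  gt_map <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(snps)), function(j) {
    d <- cohort$geno[, j]
    gt <- ifelse(is.na(d), "./.", gt_map[d + 1L])
    info <- if (nzchar(snps$gene[j])) paste0("GENE=", snps$gene[j]) else "."
    paste(c(snps$chromosome[j], snps$position[j], snps$snp_id[j],
            ref[j], counted[j], ".", "PASS", info, "GT", gt),
          collapse = "\t")
  }, character(1))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=candigene",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene region label\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cohort$samples$sample_id), collapse = "\t"))
  writeLines(c(hdr, body), vcf_path)
  write.table(cohort$samples, pheno_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(vcf = vcf_path, pheno = pheno_path))
}

#' Recode dosages so every SNP counts its minor allele
#'
#' For each SNP the counted allele becomes the allele with whole-sample
#' (cases + controls) frequency <= 0.5; where the current counted allele is
#' the major one, dosage d becomes 2 - d. Exact 0.5 ties go to the
#' lexicographically smaller base. Monomorphic SNPs are left as-is and
#' flagged in the `monomorphic` attribute.
#'
#' @param cohort a [new_cohort()] object.
#' @return The recoded `cohort`; attribute `monomorphic` is a logical vector.
#' @export
recode_to_minor <- function(cohort) {
  geno <- cohort$geno
  snps <- cohort$snps
  counted <- cohort$counted_allele
  m <- ncol(geno)
  mono <- logical(m)
  for (j in seq_len(m)) {
    d <- geno[, j]
    nn <- sum(!is.na(d))
    if (nn == 0) { mono[j] <- TRUE; next }
    p <- sum(d, na.rm = TRUE) / (2 * nn)
    other <- if (counted[j] == snps$allele_a[j]) snps$allele_b[j] else snps$allele_a[j]
    flip <- p > 0.5 || (p == 0.5 && other < counted[j])
    if (flip) {
      geno[, j] <- 2L - d
      counted[j] <- other
    }
    p_new <- if (flip) 1 - p else p
    if (p_new == 0 || p_new == 1) mono[j] <- TRUE
  }
  out <- new_cohort(snps, cohort$samples, geno, counted_allele = counted)
  attr(out, "monomorphic") <- mono
  out
}
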