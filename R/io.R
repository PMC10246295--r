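# Readers and writers for the package's standard formats. Parsers are
# strict: malformed input fails with the file, line and column named.

#' Write a genotype matrix as VCFv4.2
#'
#' Emits one biallelic record per variant with GT fields. Variants are laid
#' out on synthetic coordinates (one chromosome per block of genes) since
#' the analyses in this package are position-free.
#'
#' @param genotypes Samples-by-variants integer dosage matrix (0/1/2) with
#'   dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(genotypes, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stopf("cannot open '%s' for VCF output: %s",
                                            path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rvarch",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  samples <- rownames(genotypes) %||% character()
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", samples), collapse = "\t")
  writeLines(header, con)
  m <- ncol(genotypes)
  if (m > 0) {
    gt_codes <- c("0/0", "0/1", "1/1")
    chrom <- (seq_len(m) - 1L) %/% 1000L + 1L
    pos <- ((seq_len(m) - 1L) %% 1000L + 1L) * 100L
    ids <- colnames(genotypes) %||% sprintf("v%06d", seq_len(m))
    for (j in seq_len(m)) {
      gts <- gt_codes[genotypes[, j] + 1L]
      writeLines(paste(c(chrom[j], pos[j], ids[j], "A", "G", ".", "PASS",
                         ".", "GT", gts), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Reads a VCF via `vcfR` and returns a samples-by-variants dosage matrix.
#' Multiallelic records are split into one biallelic record per alternate
#' allele (dosage of that allele), with a message noting each split.
#'
#' @param path VCF path.
#' @return List with `genotypes` (samples x variants integer matrix) and
#'   `variants` (data frame with id, chrom, pos, ref, alt).
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stopf("VCF not found: '%s'", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samples <- colnames(vcf@gt)[-1] %||% character()
    return(list(genotypes = matrix(0L, length(samples), 0,
                                   dimnames = list(samples, NULL)),
                variants = data.frame(variant_id = character(),
                                      chrom = character(), pos = integer(),
                                      ref = character(), alt = character())))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  out_g <- list()
  out_v <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1)
      message(sprintf("splitting multiallelic record %s:%s (%d alt alleles)",
                      fix$CHROM[i], fix$POS[i], length(alts)))
    alleles <- strsplit(gsub("|", "/", gt[i, ], fixed = TRUE), "/",
                        fixed = TRUE)
    for (a in seq_along(alts)) {
      dos <- vapply(alleles, function(x) sum(x == as.character(a)), 0L)
      id <- fix$ID[i]
      if (is.na(id) || id == ".")
        id <- sprintf("%s_%s_%s_%s", fix$CHROM[i], fix$POS[i], fix$REF[i],
                      alts[a])
      else if (length(alts) > 1) id <- sprintf("%s_alt%d", id, a)
      out_g[[length(out_g) + 1L]] <- dos
      out_v[[length(out_v) + 1L]] <- data.frame(
        variant_id = id, chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[a],
        stringsAsFactors = FALSE)
    }
  }
  G <- do.call(cbind, out_g)
  variants <- do.call(rbind, out_v)
  dimnames(G) <- list(samples, variants$variant_id)
  storage.mode(G) <- "integer"
  list(genotypes = G, variants = variants)
}

#' Strict TSV reader
#'
#' Reads a tab-separated file and verifies that required columns are
#' present, failing with the file and missing column named.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @return Data frame.
#' @export
read_tsv_strict <- function(path, required = NULL) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stopf("malformed TSV '%s': %s", path,
                              conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("'%s' is missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  df
}

#' Write a TSV with optional scientific formatting of P-value columns
#'
#' @param df Data frame.
#' @param path Output path.
#' @param p_cols Columns to serialize in scientific notation with 6
#'   significant digits (cross-platform diffability of P-values).
#' @return `path`, invisibly.
#' @export
write_tsv_strict <- function(df, path, p_cols = grep("(^|_)p($|_value)",
                                                     names(df),
                                                     value = TRUE)) {
  out <- df
  for (col in intersect(p_cols, names(out)))
    if (is.numeric(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           formatC(out[[col]], format = "e", digits = 5))
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) stopf("cannot write '%s': %s", path,
                              conditionMessage(e)))
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Strict GMT parser: every line must have a set name, a description
#' column, and at least one gene; violations fail with the line number.
#'
#' @param path GMT path.
#' @return Named list of character vectors (unique gene symbols).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT not found: '%s'", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stopf("malformed GMT '%s' at line %d: expected >= 3 tab-separated fields (name, description, genes), got %d",
            path, i, length(parts))
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stopf("malformed GMT '%s' at line %d: gene set '%s' has no genes",
            path, i, parts[1])
    sets[[parts[1]]] <- genes
  }
  sets
}

#' Write gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits a VCF of genotypes, TSVs for annotations, phenotypes and ground
#' truth, and a JSON manifest recording the seed, configuration hash and
#' file inventory. Round-tripping through [read_cohort()] reproduces the
#' genotype matrix exactly and floating-point fields to text precision.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths (the manifest inventory),
#'   invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("write_cohort: cannot create directory '%s'", out_dir)
  paths <- c(genotypes = file.path(out_dir, "genotypes.vcf"),
             annotations = file.path(out_dir, "annotations.tsv"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"),
             truth_variants = file.path(out_dir, "truth_variants.tsv"),
             truth_genes = file.path(out_dir, "truth_genes.tsv"),
             truth_samples = file.path(out_dir, "truth_samples.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  write_vcf_genotypes(cohort$genotypes, paths["genotypes"])
  write_tsv_strict(cohort$annotations, paths["annotations"])
  write_tsv_strict(cohort$samples, paths["phenotypes"])
  write_tsv_strict(cohort$truth$variants, paths["truth_variants"])
  write_tsv_strict(cohort$truth$genes, paths["truth_genes"])
  write_tsv_strict(cohort$truth$samples, paths["truth_samples"])
  manifest <- list(seed = cohort$config$seed,
                   config_hash = config_hash(cohort$config),
                   n_samples = nrow(cohort$samples),
                   n_cases = sum(cohort$samples$status == 1),
                   n_variants = ncol(cohort$genotypes),
                   mody_genes = cohort$mody_genes,
                   files = as.list(basename(paths)))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return List of class `synthetic_cohort` (without the generating
#'   configuration, which is summarized by its hash in the manifest).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  g <- read_vcf_genotypes(file.path(dir, "genotypes.vcf"))
  ann <- read_tsv_strict(file.path(dir, "annotations.tsv"),
                         required = c("variant_id", "gene", "category",
                                      "pathogenic_flag"))
  samp <- read_tsv_strict(file.path(dir, "phenotypes.tsv"),
                          required = c("sample_id", "status", "cluster"))
  truth <- list(
    variants = read_tsv_strict(file.path(dir, "truth_variants.tsv"),
                               required = c("variant_id", "beta_true")),
    genes = read_tsv_strict(file.path(dir, "truth_genes.tsv"),
                            required = c("gene", "class")),
    samples = read_tsv_strict(file.path(dir, "truth_samples.tsv"),
                              required = "sample_id"))
  G <- g$genotypes
  # VCF row order is preserved; align to annotation order defensively
  if (ncol(G) && !identical(colnames(G), ann$variant_id))
    G <- G[, ann$variant_id, drop = FALSE]
  if (nrow(G) && !identical(rownames(G), samp$sample_id))
    G <- G[samp$sample_id, , drop = FALSE]
  structure(list(genotypes = G, annotations = ann, samples = samp,
                 truth = truth,
                 mody_genes = unlist(manifest$mody_genes),
                 manifest = manifest),
            class = "synthetic_cohort")
}
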