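# plain-text interchange: phenotype TSV, genotype dosage TSV with a
# metadata header block, catalogue / gene / summary-stat tables

#' Write and read the phenotype table
#'
#' One row per individual; columns: id, sex, covariates, proxies, target,
#' measured flag.
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @export
write_phenotypes <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write and read the genotype dosage store
#'
#' Dosage TSV with variants as columns. Variant metadata (chr, pos, a1, a0,
#' eaf, info) is stored in `##`-prefixed header lines, one per field, so a
#' single plain-text file round-trips the full `genotype_matrix`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path file path.
#' @export
write_genotypes <- function(genotypes, path) {
  v <- genotypes$variants
  con <- file(path, "w")
  on.exit(close(con))
  for (f in c("chr", "pos", "a1", "a0", "eaf", "info"))
    writeLines(paste0("##", f, "\t", paste(v[[f]], collapse = "\t")), con)
  writeLines(paste(v$id, collapse = "\t"), con)
  utils::write.table(genotypes$dosages, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  lines <- readLines(path)
  metal <- grep("^##", lines, value = TRUE)
  meta <- list()
  for (l in metal) {
    parts <- strsplit(sub("^##", "", l), "\t")[[1]]
    meta[[parts[1]]] <- parts[-1]
  }
  body <- lines[!grepl("^##", lines)]
  header <- strsplit(body[1], "\t")[[1]]
  dat <- utils::read.delim(text = paste(body[-1], collapse = "\n"),
                           header = FALSE, col.names = header)
  dosages <- as.matrix(dat)
  colnames(dosages) <- header
  variants <- data.frame(id = header, chr = meta$chr,
                         pos = as.integer(meta$pos), a1 = meta$a1,
                         a0 = meta$a0, eaf = as.numeric(meta$eaf),
                         info = as.numeric(meta$info), stringsAsFactors = FALSE)
  new_genotype_matrix(dosages, variants)
}

#' Write a GWAS result table
#'
#' Fixed column order: rsid, chr, pos, a1, a0, freq1, info, n, beta1, se, p
#' (1-based positions).
#'
#' @param gwas a [run_gwas()] result.
#' @param path file path.
#' @export
write_gwas <- function(gwas, path) {
  cols <- c("rsid", "chr", "pos", "a1", "a0", "freq1", "info", "n",
            "beta1", "se", "p")
  utils::write.table(as.data.frame(gwas)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known-association catalogue or gene annotation table
#'
#' Catalogue columns: chr, pos (1-based), plus free annotation columns.
#' Gene table columns: chr, start, end, name (1-based inclusive). BED input
#' (`.bed` suffix: chr, start, end, name, 0-based half-open) is converted
#' to 1-based inclusive on read.
#'
#' @param path file path.
#' @export
read_catalogue <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_catalogue
#' @export
read_gene_table <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    g <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(g)[1:4] <- c("chr", "start", "end", "name")
    g$chr <- sub("^chr", "", g$chr)
    g$start <- g$start + 1L  # 0-based half-open -> 1-based inclusive
    return(g)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# flat key: value text block for the simulation truth
write_truth <- function(truth, path) {
  kv <- c(
    causal_id = paste(truth$causal_id, collapse = ","),
    causal_index = paste(truth$causal_index, collapse = ","),
    b = paste(truth$b, collapse = ","),
    delta = paste(truth$delta, collapse = ","),
    r2_theory_male = truth$r2_theory[["male"]],
    r2_theory_female = truth$r2_theory[["female"]],
    alpha_male = truth$alpha[["male"]],
    alpha_female = truth$alpha[["female"]],
    seed = truth$config$seed)
  writeLines(paste0(names(kv), ": ", unname(kv)), path)
  invisible(path)
}
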