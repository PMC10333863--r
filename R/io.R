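#' Binned count matrix container
#'
#' Holds per-individual read counts in fixed-width genomic bins together with
#' bin coordinates (0-based half-open), library sizes in millions of reads,
#' and an index set of excluded bins (e.g. VDJ regions).
#'
#' @param counts integer matrix, individuals x bins (non-negative).
#' @param bins data.frame with columns `chrom`, `start`, `end`; all bins the
#'   same width, sorted and non-overlapping within chromosome.
#' @param lib_size_millions numeric vector of library sizes (millions of
#'   reads), one per individual; computed from row sums if missing.
#' @param excluded_bins integer indices of bins excluded from analysis.
#' @return An object of class `binned_counts`.
#' @export
binned_counts <- function(counts, bins, lib_size_millions = NULL,
                          excluded_bins = integer(0)) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop_ca("counts must be non-negative")
  if (ncol(counts) != nrow(bins))
    stop_ca("counts has %d columns but bins has %d rows", ncol(counts), nrow(bins))
  widths <- bins$end - bins$start
  if (length(unique(widths)) != 1L)
    stop_ca("all bins must have the same width; found widths %s",
            paste(unique(widths), collapse = ", "))
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE) || any(diff(b$start) < widths[1]))
      stop_ca("bins on %s must be sorted and non-overlapping", ch)
  }
  if (is.null(lib_size_millions))
    lib_size_millions <- rowSums(counts) / 1e6
  if (any(lib_size_millions <= 0)) stop_ca("lib_size_millions must be positive")
  if (length(lib_size_millions) != nrow(counts))
    stop_ca("one library size per individual required")
  structure(list(counts = counts, bins = bins,
                 lib_size_millions = lib_size_millions,
                 excluded_bins = as.integer(excluded_bins)),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("Binned count matrix: %d individuals x %d bins (%d bp), %d excluded\n",
              nrow(x$counts), ncol(x$counts),
              x$bins$end[1] - x$bins$start[1], length(x$excluded_bins)))
  invisible(x)
}

#' Read a BED file (BED3-BED6)
#'
#' Coordinates are kept 0-based half-open as in the format. Track and
#' comment lines are skipped. Malformed lines raise an error naming the line
#' number.
#'
#' @param path file path.
#' @param strict if TRUE, zero-width intervals (`start == end`) are rejected.
#' @return data.frame with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path, strict = FALSE) {
  lines <- readLines(path)
  skip <- grepl("^(track|browser|#)", lines) | lines == ""
  n_skipped <- sum(skip)
  body <- lines[!skip]
  line_no <- which(!skip)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (length(body) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop_ca("malformed BED line %d in %s: fewer than 3 fields", line_no[which(nf < 3L)[1]], path)
  k <- min(max(nf), 6L)
  m <- t(vapply(parts, function(p) c(p, rep(NA_character_, 6))[1:6], character(6)))
  out <- data.frame(chrom = m[, 1], start = suppressWarnings(as.integer(m[, 2])),
                    end = suppressWarnings(as.integer(m[, 3])),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end))
    stop_ca("malformed BED line %d in %s: non-integer coordinates",
            line_no[which(is.na(out$start) | is.na(out$end))[1]], path)
  if (any(out$end < out$start))
    stop_ca("malformed BED line %d in %s: end < start",
            line_no[which(out$end < out$start)[1]], path)
  if (strict && any(out$end == out$start))
    stop_ca("BED line %d in %s: zero-width interval in strict mode",
            line_no[which(out$end == out$start)[1]], path)
  if (k >= 4L && !all(is.na(m[, 4]))) out$name <- m[, 4]
  if (k >= 5L && !all(is.na(m[, 5]))) out$score <- suppressWarnings(as.numeric(m[, 5]))
  if (k >= 6L && !all(is.na(m[, 6]))) out$strand <- m[, 6]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write an interval table as BED
#'
#' @param table data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` (0-based half-open).
#' @param path output path.
#' @param header optional comment line written first (prefixed with `#`).
#' @return the path, invisibly.
#' @export
write_bed <- function(table, path, header = NULL) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(table))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(table) > 0L) {
    m <- table[, cols, drop = FALSE]
    writeLines(do.call(paste, c(lapply(m, as.character), sep = "\t")), con)
  }
  invisible(path)
}

#' Write per-individual signal as bedGraph
#' @param values numeric vector, one per bin.
#' @param bins bin coordinate data.frame (`chrom`, `start`, `end`).
#' @param path output path.
#' @param name track name.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(values, bins, path, name = "signal") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  ok <- is.finite(values)
  writeLines(paste(bins$chrom[ok], bins$start[ok], bins$end[ok],
                   format(values[ok], digits = 8, trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' Read a genotype matrix from VCF or TSV
#'
#' VCF input (v4.x, GT field) is parsed with \pkg{vcfR}; multiallelic sites
#' are skipped with a warning giving their count. TSV input must have SNPs as
#' rows, columns `id`, `chrom`, `pos` followed by one dosage column per
#' individual. Dosages are 0/1/2 with missing genotypes recorded as NA; the
#' minor allele frequency is computed from non-missing calls.
#'
#' @param path input path; format chosen by extension (`.vcf` vs other).
#' @return a list with `dosages` (individuals x SNPs) and `snp_table`
#'   (`id`, `chrom`, `pos`, `maf`).
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(v)
    multi <- grepl(",", alt %||% "")
    if (any(multi)) {
      warning(sprintf("skipping %d multiallelic site(s)", sum(multi)))
      v <- v[!multi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(x) {
      if (is.na(x) || grepl("\\.", x)) return(NA_integer_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]))
    })
    fix <- vcfR::getFIX(v)
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(fix[is.na(ids) | ids == ".", "CHROM"],
                                           "_", fix[is.na(ids) | ids == ".", "POS"])
    dosages <- t(dos)
    colnames(dosages) <- ids
    snp_table <- data.frame(id = ids, chrom = fix[, "CHROM"],
                            pos = as.integer(fix[, "POS"]) - 1L,
                            stringsAsFactors = FALSE)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    meta <- c("id", "chrom", "pos")
    if (!all(meta %in% names(tab)))
      stop_ca("genotype TSV must have columns id, chrom, pos")
    dosages <- t(as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE]))
    colnames(dosages) <- tab$id
    snp_table <- tab[, meta]
  }
  af <- colMeans(dosages, na.rm = TRUE) / 2
  snp_table$maf <- pmin(af, 1 - af)
  list(dosages = dosages, snp_table = snp_table)
}

#' Write genotypes as a minimal VCF v4.2 (GT field only)
#' @param dosages individuals x SNPs matrix of 0/1/2 (NA allowed).
#' @param snp_table data.frame with `id`, `chrom`, `pos` (0-based).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(dosages, snp_table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dosages)), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (s in seq_len(ncol(dosages))) {
    g <- dosages[, s]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(snp_table$chrom[s], snp_table$pos[s] + 1L,
                       snp_table$id[s], "A", "G", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write gene models as GTF
#' @param gene_models data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open; converted to GTF 1-based closed).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gtf <- function(gene_models, path) {
  lines <- sprintf('%s\tcoactivity\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   gene_models$chrom, gene_models$start + 1L, gene_models$end,
                   gene_models$strand, gene_models$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write a numeric matrix as TSV (features as rows, individuals as columns)
#' @param m matrix with dimnames.
#' @param path output path.
#' @param feature_col name of the leading feature-id column.
#' @param header optional comment line (config hash / seed provenance).
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(m, path, feature_col = "feature", header = NULL) {
  df <- data.frame(rownames_ = colnames(m), t(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA"))
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path input path.
#' @return matrix, individuals x features.
#' @export
read_matrix_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE)
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(m) <- tab[[1]]
  m
}

#' Read a binned count matrix from TSV + bin BED
#' @param counts_path TSV with bins as rows, individuals as columns (leading
#'   column = bin id).
#' @param bins_path BED3 file defining the bins, in the same order.
#' @param lib_size_millions optional library sizes; row sums / 1e6 if absent.
#' @return a [binned_counts()] object.
#' @export
read_counts <- function(counts_path, bins_path, lib_size_millions = NULL) {
  m <- read_matrix_tsv(counts_path)
  bins <- read_bed(bins_path)
  binned_counts(m, bins[, c("chrom", "start", "end")], lib_size_millions)
}

#' Write all simulated fixtures to a directory
#'
#' Emits counts (TSV + per-individual bedGraph), genotypes (minimal VCF),
#' gene models (GTF + TSV), annotation tracks (BED), and truth tables (TSV),
#' and returns a manifest listing paths and md5 checksums. The manifest hash
#' changes whenever any field of the truth changes.
#'
#' @param truth a `sim_truth` object from [simulate_dataset()].
#' @param counts the matching [binned_counts()] object.
#' @param out_dir output directory (created if needed).
#' @return the manifest (named list), invisibly written to
#'   `manifest.json` in `out_dir`.
#' @export
write_fixtures <- function(truth, counts, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bins <- counts$bins
  paths <- character(0)
  emit <- function(p) { paths[length(paths) + 1L] <<- p; p }

  write_bed(bins, emit(file.path(out_dir, "bins.bed")))
  write_matrix_tsv(counts$counts, emit(file.path(out_dir, "counts.tsv")),
                   feature_col = "bin")
  for (j in rownames(counts$counts))
    write_bedgraph(counts$counts[j, ], bins,
                   emit(file.path(out_dir, paste0("coverage_", j, ".bedGraph"))),
                   name = j)
  write_vcf(truth$genotypes, truth$snp_table,
            emit(file.path(out_dir, "genotypes.vcf")))
  write_gtf(truth$gene_models, emit(file.path(out_dir, "genes.gtf")))
  write.table(truth$gene_models, emit(file.path(out_dir, "genes.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(truth$annotation_tracks)) {
    tr <- truth$annotation_tracks[[nm]]
    if (nm == "compartments") tr$name <- tr$class
    write_bed(tr, emit(file.path(out_dir, paste0(nm, ".bed"))),
              header = if (nrow(tr) == 0L) sprintf("empty track: %s", nm) else NULL)
  }
  write_matrix_tsv(truth$pd_true, emit(file.path(out_dir, "pd_true.tsv")), "bin")
  write_matrix_tsv(truth$pi_true, emit(file.path(out_dir, "pi_true.tsv")), "bin")
  write_matrix_tsv(truth$tf_expression,
                   emit(file.path(out_dir, "tf_expression.tsv")), "tf")
  write_matrix_tsv(truth$expression, emit(file.path(out_dir, "expression_tpm.tsv")),
                   "gene")
  write_matrix_tsv(truth$abc_counts, emit(file.path(out_dir, "abc_counts.tsv")),
                   "gene")
  write_matrix_tsv(truth$histone_signal,
                   emit(file.path(out_dir, "histone_signal.tsv")), "bin")
  write.table(truth$domain_intervals, emit(file.path(out_dir, "domains_true.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$qtl_effects, emit(file.path(out_dir, "qtl_effects.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(individual = names(counts$lib_size_millions),
                         lib_size_millions = counts$lib_size_millions),
              emit(file.path(out_dir, "lib_sizes.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sums <- tools::md5sum(paths)
  manifest <- list(
    files = data.frame(path = basename(paths), md5 = unname(sums),
                       stringsAsFactors = FALSE),
    manifest_md5 = unname(tools::md5sum(
      textConnection_md5(paste(basename(paths), sums, collapse = "\n")))),
    seed = truth$config$seed
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

# md5 of a string via a temp file (tools::md5sum works on files only)
textConnection_md5 <- function(x) {
  tf <- tempfile()
  writeLines(x, tf)
  tf
}
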