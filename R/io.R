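# Readers and writers. Conventions: bp positions are 0-based half-open
# internally and in BED output; VCF output is 1-based. Genotypes travel as
# a tab-separated matrix (lines x markers) or as VCF (read via the vcfR
# package when installed); maps, phenotypes and IBD segments as TSV.

.check_file <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  invisible(path)
}

#' Write / read a genetic map as TSV
#'
#' Columns `chrom`, `marker`, `bp`, `cm`; chromosome extents are stored in
#' `#length chrom bp cm` header comment lines so a map round-trips exactly.
#' @param map a `genetic_map`
#' @param path file path
#' @export
write_map <- function(map, path) {
  hdr <- sprintf("#length\t%s\t%.0f\t%g", map_chromosomes(map),
                 chrom_lengths(map, "bp"), chrom_lengths(map, "cm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(as.data.frame(map)[, c("chrom", "marker", "bp", "cm")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  .check_file(path)
  lines <- readLines(path)
  hl <- grep("^#length", lines, value = TRUE)
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  len_bp <- len_cm <- NULL
  if (length(hl)) {
    parts <- do.call(rbind, strsplit(hl, "\t"))
    len_bp <- setNames(as.numeric(parts[, 3]), parts[, 2])
    len_cm <- setNames(as.numeric(parts[, 4]), parts[, 2])
  }
  genetic_map(df, chrom_len_bp = len_bp, chrom_len_cm = len_cm)
}

#' Write / read a genotype matrix as TSV
#'
#' Lines as rows (first column `id`), markers as columns.
#' @param geno lines (or founders) x markers matrix
#' @param path file path
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(id = rownames(geno) %||% paste0("L", seq_len(nrow(geno))),
                   geno, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  .check_file(path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  mode(g) <- "numeric"
  rownames(g) <- df[[1]]
  g
}

#' Write genotypes as a minimal VCF
#'
#' Haploid founder/DH genotypes are written as homozygous diploid calls
#' (0/0 or 1/1) with placeholder REF/ALT alleles; positions are 1-based.
#' @param geno lines x markers 0/1 matrix
#' @param map a `genetic_map` matching the columns
#' @param path output file (plain text)
#' @export
write_vcf <- function(geno, map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%.0f>", map_chromosomes(map),
                       chrom_lengths(map, "bp")),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  ids <- rownames(geno) %||% paste0("L", seq_len(nrow(geno)))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  gt <- matrix(c("0/0", "1/1")[geno + 1], nrow(geno))
  gt[is.na(geno)] <- "./."
  body <- paste(map$chrom, format(map$bp + 1, scientific = FALSE, trim = TRUE),
                map$marker, "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Requires the vcfR package. Homozygous diploid (0/0, 1/1) and haploid
#' (0, 1) calls are accepted; heterozygous calls become NA.
#' @param path VCF file
#' @return list with `geno` (lines x markers) and `positions` data.frame
#' @export
read_vcf_genotypes <- function(path) {
  .check_file(path)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_invalid("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  conv <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% c("0", "0/0")] <- 0
    out[x %in% c("1", "1/1")] <- 1
    out
  }
  g <- t(apply(gt, 2, conv))
  colnames(g) <- rownames(gt)
  rownames(g) <- colnames(gt)
  pos <- data.frame(chrom = vcfR::getCHROM(v), marker = rownames(gt),
                    bp = as.numeric(vcfR::getPOS(v)) - 1,
                    stringsAsFactors = FALSE)
  list(geno = g, positions = pos)
}

#' Write ancestry mosaics as BED
#'
#' One row per segment: chrom, start, end (0-based half-open), name =
#' `line|founder`, score = founder index.
#' @param pop a `magic_population`
#' @param path output file
#' @export
write_mosaics_bed <- function(pop, path) {
  fids <- pop$founder_ids
  rows <- lapply(names(pop$mosaics), function(ln) {
    d <- as.data.frame(pop$mosaics[[ln]])
    data.frame(chrom = d$chrom, start = format(d$start, scientific = FALSE),
               end = format(d$end, scientific = FALSE),
               name = paste(ln, fids[d$founder], sep = "|"),
               score = d$founder, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write haplotype blocks as BED
#'
#' name = semicolon-joined founder groups (founders within a group joined
#' by commas), score = number of distinct haplotypes.
#' @param blocks a `haplotype_blocks` object
#' @param path output file
#' @export
write_blocks_bed <- function(blocks, path) {
  b <- blocks$blocks
  nm <- vapply(blocks$groups, function(g) {
    paste(vapply(split(names(g), g), paste, "", collapse = ","),
          collapse = ";")
  }, "")
  out <- data.frame(chrom = b$chrom,
                    start = format(b$start_bp, scientific = FALSE),
                    end = format(b$end_bp, scientific = FALSE),
                    name = nm, score = b$n_hap, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write / read a long-format phenotype table as TSV
#' @param pheno data.frame with `line`, `env`, `rep`, `value`
#' @param path file path
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  .check_file(path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("line", "env", "value") %in% names(df)))
    stop_invalid("phenotype file needs line, env, value columns")
  df
}

#' Write a genome scan as TSV
#' @param scan a `magic_scan`
#' @param path file path
#' @export
write_scan <- function(scan, path) {
  write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Load and align a dataset from files
#'
#' Reads founder genotypes, line genotypes (TSV matrix or VCF by file
#' extension), the genetic map and the phenotype table, restricts all
#' genotypes to the markers present in the map (markers missing from any
#' source are dropped with a message), and returns the aligned pieces.
#'
#' @param config list with paths: `map`, `founder_geno`, `line_geno`,
#'   `phenotypes` (optional), `ibd_segments` (optional)
#' @return list with `map`, `founders` (a `founder_set`), `line_geno`,
#'   `pheno`, `ibd`
#' @export
load_dataset <- function(config) {
  map <- read_map(.check_file(config$map))
  read_geno <- function(path) {
    if (grepl("\\.vcf$", path, ignore.case = TRUE))
      read_vcf_genotypes(path)$geno
    else read_genotypes(path)
  }
  fg <- read_geno(.check_file(config$founder_geno))
  lg <- read_geno(.check_file(config$line_geno))
  common <- Reduce(intersect, list(map$marker, colnames(fg), colnames(lg)))
  if (!length(common))
    stop_invalid("no common markers between map, founder and line genotypes; ",
                 "first map markers: ",
                 paste(head(map$marker, 3), collapse = ", "))
  dropped <- length(map$marker) - length(common)
  if (dropped > 0)
    message(dropped, " marker(s) dropped while aligning genotypes to the map")
  keep <- map$marker %in% common
  map2 <- genetic_map(as.data.frame(map)[keep, ],
                      chrom_len_bp = chrom_lengths(map, "bp"),
                      chrom_len_cm = chrom_lengths(map, "cm"))
  founders <- founder_set(fg[, map2$marker, drop = FALSE], map2)
  lg <- lg[, map2$marker, drop = FALSE]
  pheno <- if (!is.null(config$phenotypes))
    read_phenotypes(config$phenotypes) else NULL
  ibd <- if (!is.null(config$ibd_segments))
    read_ibd_segments(config$ibd_segments, founder_ids(founders)) else NULL
  list(map = map2, founders = founders, line_geno = lg, pheno = pheno,
       ibd = ibd)
}
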