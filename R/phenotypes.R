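# Phenotype simulation with planted QTL of bi-allelic, founder, or
# ancestral-haplotype architecture over a polygenic background, observed in
# multiple environments with replicates.

#' Specify a planted QTL
#'
#' @param chrom,bp locus position (must lie on the map)
#' @param architecture `"biallelic"`, `"founder"`, or `"haplotype"`
#' @param var_frac fraction of phenotypic variance explained by the QTL
#' @param effects optional raw per-allele effects: length 2 (biallelic),
#'   length f (founder) or length n_haplotypes of the enclosing block
#'   (haplotype). The realized line scores are rescaled so the QTL
#'   explains `var_frac` of the phenotypic variance, so only the pattern
#'   matters.
#' @param carriers for founder/haplotype architectures, an alternative to
#'   `effects`: indices of the allele-carrying founders (or haplotype
#'   groups); carriers get effect 1, non-carriers 0.
#' @return object of class `qtl_spec`
#' @export
qtl_spec <- function(chrom, bp, architecture = c("biallelic", "founder", "haplotype"),
                     var_frac, effects = NULL, carriers = NULL) {
  architecture <- match.arg(architecture)
  if (var_frac < 0 || var_frac > 1) stop_invalid("var_frac must be in [0, 1]")
  if (is.null(effects) && is.null(carriers) && architecture != "biallelic")
    stop_invalid("give either effects or carriers")
  structure(list(chrom = as.character(chrom), bp = bp,
                 architecture = architecture, var_frac = var_frac,
                 effects = effects, carriers = carriers),
            class = "qtl_spec")
}

# per-line raw genetic score of one QTL
.qtl_score <- function(q, pop, founders, blocks, geno) {
  map <- pop$map
  if (!q$chrom %in% map_chromosomes(map) ||
      q$bp < 0 || q$bp >= chrom_lengths(map, "bp")[[q$chrom]])
    stop_invalid("QTL locus off the map: ", q$chrom, ":", q$bp)
  idx <- which(map$chrom == q$chrom)
  j <- idx[which.min(abs(map$bp[idx] - q$bp))]  # nearest marker
  fo <- vapply(pop$mosaics, function(m) mosaic_founder_at(m, q$chrom, map$bp[j]), 1)
  if (q$architecture == "biallelic") {
    allele <- geno[, j]
    eff <- q$effects %||% c(0, 1)
    return(eff[allele + 1])
  }
  f <- pop$scheme$n_founders
  if (q$architecture == "founder") {
    eff <- q$effects %||% as.numeric(seq_len(f) %in% q$carriers)
    if (length(eff) != f) stop_invalid("founder QTL needs ", f, " effects")
    return(eff[fo])
  }
  if (is.null(blocks)) stop_invalid("haplotype QTL needs a haplotype block set")
  grp <- .block_grouping_at(blocks, q$chrom, map$bp[j])
  h <- max(grp)
  eff <- q$effects %||% as.numeric(seq_len(h) %in% q$carriers)
  if (length(eff) != h)
    stop_invalid("haplotype QTL needs ", h, " effects at this block")
  eff[grp[fo]]
}

#' Simulate phenotypes for a MAGIC population
#'
#' The observation for line i in environment j, replicate k is
#' `mu + sum of QTL scores + polygenic value + environment effect +
#' residual`. The phenotypic variance (at the observation level, excluding
#' the environment term) is normalized to 1: each QTL contributes its
#' `var_frac`, the polygenic term (multivariate normal with covariance
#' proportional to the realized genomic relationship matrix) contributes
#' `h2_poly`, and the residual takes the remainder.
#'
#' @param pop a `magic_population`
#' @param founders a `founder_set`
#' @param qtl list of `qtl_spec` objects (may be empty)
#' @param h2_poly polygenic heritability (default 0.3)
#' @param n_env,n_rep environments and replicates per environment
#' @param env_var variance of environment main effects (default 0)
#' @param resid_var residual variance per observation; defaults to
#'   `1 - sum(var_frac) - h2_poly` so the phenotypic variance is 1. Set it
#'   explicitly (e.g. 0) to leave the normalized scale.
#' @param blocks optional `haplotype_blocks`, required for haplotype QTL
#' @param mu grand mean (default 0)
#' @param seed optional RNG seed
#' @return long-format data.frame (`line`, `env`, `rep`, `value`) with the
#'   per-line genetic values attached as attribute `"truth"`
#' @export
simulate_phenotypes <- function(pop, founders, qtl = list(), h2_poly = 0.3,
                                n_env = 1, n_rep = 1, env_var = 0,
                                resid_var = NULL, blocks = NULL, mu = 0,
                                seed = NULL) {
  set_seed_if(seed)
  if (inherits(qtl, "qtl_spec")) qtl <- list(qtl)
  vq <- vapply(qtl, function(q) q$var_frac, 1)
  resid_var <- resid_var %||% (1 - sum(vq) - h2_poly)
  if (resid_var < 0) stop_invalid("variance fractions sum to more than 1")
  n <- length(pop$mosaics)
  lines <- names(pop$mosaics)
  geno <- mosaic_to_genotypes(pop, founders)

  g <- numeric(n)
  for (q in qtl) {
    raw <- .qtl_score(q, pop, founders, blocks, geno)
    s <- sd(raw)
    if (s == 0) {
      if (q$var_frac > 0)
        warning("QTL at ", q$chrom, ":", q$bp,
                " is monomorphic in the population; contributes no variance")
      next
    }
    g <- g + (raw - mean(raw)) / s * sqrt(q$var_frac)
  }

  if (h2_poly > 0) {
    K <- compute_grm(geno, map = pop$map)
    L <- chol(K + diag(1e-6, n))
    u <- drop(crossprod(L, rnorm(n)))
    u <- (u - mean(u)) / sd(u) * sqrt(h2_poly)
  } else u <- numeric(n)

  envs <- paste0("env", seq_len(n_env))
  env_eff <- if (env_var > 0) rnorm(n_env, 0, sqrt(env_var)) else numeric(n_env)
  out <- expand.grid(line = lines, env = envs, rep = seq_len(n_rep),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  li <- match(out$line, lines)
  ei <- match(out$env, envs)
  eps <- if (resid_var > 0) rnorm(nrow(out), 0, sqrt(resid_var)) else 0
  out$value <- mu + g[li] + u[li] + env_eff[ei] + eps
  attr(out, "truth") <- data.frame(line = lines, qtl_value = g,
                                   polygenic = u, stringsAsFactors = FALSE)
  class(out) <- c("pheno_table", "data.frame")
  out
}
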