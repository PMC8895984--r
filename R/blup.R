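# Best linear unbiased prediction of line genetic values across
# environments: a two-way model with environment as a fixed effect and
# line as a random intercept, variance components by REML (lme4).

#' Per-line BLUPs across environments and replicates
#'
#' Fits `value ~ env + (1 | line)` (or an intercept-only fixed part when a
#' single environment is present) and returns the predicted random line
#' effects shifted by the grand mean, so the BLUPs live on the phenotype
#' scale. Lines with no observations are dropped with a warning.
#'
#' @param pheno long-format data.frame with columns `line`, `env`, `value`
#'   (replicates are simply extra rows)
#' @return data.frame with columns `line` and `blup`
#' @examples
#' ph <- data.frame(line = rep(c("a", "b"), each = 4),
#'                  env = rep(c("e1", "e2"), 4),
#'                  value = rnorm(8))
#' calc_blups(ph)
#' @export
calc_blups <- function(pheno) {
  need <- c("line", "env", "value")
  if (!all(need %in% names(pheno)))
    stop_invalid("phenotype table needs columns ", paste(need, collapse = ", "))
  all_lines <- unique(as.character(pheno$line))
  pheno <- pheno[!is.na(pheno$value), , drop = FALSE]
  if (length(all_lines) < 2L) stop_invalid("need at least 2 lines")
  pheno$line <- factor(pheno$line)
  pheno$env <- factor(pheno$env)
  form <- if (nlevels(pheno$env) > 1L) value ~ env + (1 | line)
          else value ~ (1 | line)
  fit <- suppressMessages(lme4::lmer(form, data = pheno))
  u <- lme4::ranef(fit)$line
  fe <- lme4::fixef(fit)
  # grand mean = average of the environment means
  env_means <- fe[["(Intercept)"]] +
    c(0, fe[grep("^env", names(fe))])
  gm <- mean(env_means)
  out <- data.frame(line = rownames(u), blup = gm + u[["(Intercept)"]],
                    stringsAsFactors = FALSE)
  missing <- setdiff(all_lines, out$line)
  if (length(missing))
    warning(length(missing), " line(s) without observations dropped: ",
            paste(head(missing, 5), collapse = ", "))
  rownames(out) <- NULL
  out
}
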