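## Run expr with a temporary RNG state seeded at `seed`; restores the
## caller's stream afterwards so independent analyses do not interact.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
        else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

## Exact REML for the one-way random-intercept model y = mu + g + e,
## profiled over the variance ratio lambda = sigma2_g / sigma2_e.
## For balanced designs the optimum coincides with the ANOVA
## (MSB - MSW)/r estimator truncated at zero.
.remlOneWay <- function(y, group) {
    group <- as.integer(factor(group))
    n <- length(y)
    ni <- tabulate(group)
    ybar <- rowsum(y, group)[, 1L] / ni
    ssw <- sum((y - ybar[group])^2)
    crit <- function(lambda) {
        wi <- ni / (1 + lambda * ni)
        sw <- sum(wi)
        mu <- sum(wi * ybar) / sw
        s2 <- (ssw + sum(wi * (ybar - mu)^2)) / (n - 1)
        (n - 1) * log(s2) + sum(log1p(lambda * ni)) + log(sw)
    }
    opt <- stats::optimize(function(t) crit(exp(t)),
                           interval = c(-30, 15), tol = 1e-12)
    lam <- exp(opt$minimum)
    if (crit(0) <= opt$objective) lam <- 0
    wi <- ni / (1 + lam * ni)
    mu <- sum(wi * ybar) / sum(wi)
    s2e <- (ssw + sum(wi * (ybar - mu)^2)) / (n - 1)
    list(sigma2_g = lam * s2e, sigma2_e = s2e)
}

.designFactors <- function(design) {
    d <- as.data.frame(design)
    stopifnot("individual" %in% colnames(d))
    geno <- factor(d$individual)
    expf <- if (!is.null(d$experiment)) factor(d$experiment)
            else factor(rep("E1", nrow(d)))
    rowf <- if (!is.null(d$row))
        factor(paste(as.character(expf), d$row, sep = ":")) else NULL
    colf <- if (!is.null(d$column))
        factor(paste(as.character(expf), d$column, sep = ":")) else NULL
    if (!is.null(rowf) && nlevels(rowf) < 2L) rowf <- NULL
    if (!is.null(colf) && nlevels(colf) < 2L) colf <- NULL
    list(geno = geno, expf = expf, rowf = rowf, colf = colf)
}

#' REML variance components for one expression trait
#'
#' Fits the random-intercept mixed model with an intercept, a fixed
#' experiment effect (when more than one experiment is present) and random
#' genotype, row-within-experiment and column-within-experiment effects,
#' and returns the REML variance components. Row/column terms that do not
#' vary in the design are dropped. When only the genotype term remains the
#' fit uses an exact profiled one-way REML; otherwise \code{lme4::lmer}
#' (REML) is used. Negative estimates cannot occur (both optimizers bound
#' variances at zero). Degenerate inputs (a single genotype, or a constant
#' trait) return all-zero components with \code{flag = "degenerate"}.
#'
#' @param y numeric trait vector, one value per sample.
#' @param design data.frame aligned with `y`; columns `individual`
#'   (genotype), optional `row`, `column`, `experiment`.
#' @param engine `"auto"` (default), `"lmer"` or `"oneway"` to force a
#'   backend.
#' @return list with `sigma2_g`, `sigma2_r`, `sigma2_c`, `sigma2_e`, `h2`
#'   and `flag` (`""` or `"degenerate"`).
#' @export
fitVarianceComponents <- function(y, design,
                                  engine = c("auto", "lmer", "oneway")) {
    engine <- match.arg(engine)
    stopifnot(length(y) == nrow(as.data.frame(design)))
    f <- .designFactors(design)
    zero <- list(sigma2_g = 0, sigma2_r = 0, sigma2_c = 0, sigma2_e = 0,
                 h2 = 0, flag = "degenerate")
    if (nlevels(f$geno) < 2L || stats::sd(y) == 0) return(zero)
    oneway <- is.null(f$rowf) && is.null(f$colf) && nlevels(f$expf) < 2L
    if (engine == "oneway" || (engine == "auto" && oneway)) {
        r <- .remlOneWay(y, f$geno)
        vc <- list(sigma2_g = r$sigma2_g, sigma2_r = 0, sigma2_c = 0,
                   sigma2_e = r$sigma2_e)
    } else {
        dat <- data.frame(y = y, geno = f$geno, expf = f$expf)
        rhs <- "(1 | geno)"
        if (!is.null(f$rowf)) {
            dat$rowf <- f$rowf
            rhs <- c(rhs, "(1 | rowf)")
        }
        if (!is.null(f$colf)) {
            dat$colf <- f$colf
            rhs <- c(rhs, "(1 | colf)")
        }
        fixed <- if (nlevels(f$expf) > 1L) "expf" else "1"
        form <- stats::as.formula(
            paste("y ~", fixed, "+", paste(rhs, collapse = " + ")))
        fit <- suppressMessages(suppressWarnings(lme4::lmer(
            form, data = dat, REML = TRUE,
            control = lme4::lmerControl(calc.derivs = FALSE,
                                        check.conv.singular = "ignore"))))
        vd <- as.data.frame(lme4::VarCorr(fit))
        pick <- function(g) {
            v <- vd$vcov[vd$grp == g]
            if (length(v)) v[1L] else 0
        }
        vc <- list(sigma2_g = pick("geno"), sigma2_r = pick("rowf"),
                   sigma2_c = pick("colf"), sigma2_e = pick("Residual"))
    }
    vc$h2 <- broadSenseH2(vc$sigma2_g, vc$sigma2_r, vc$sigma2_c, vc$sigma2_e)
    vc$flag <- ""
    vc
}

#' Broad-sense heritability from variance components
#'
#' The genotypic fraction of total phenotypic variance,
#' \eqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_r + \sigma^2_c +
#' \sigma^2_e)}. Zero total variance gives 0 by convention. Negative
#' components are a validation error (truncation happens in the fitter).
#'
#' @param sigma2_g,sigma2_r,sigma2_c,sigma2_e non-negative variance
#'   components (genotype, row, column, residual).
#' @return numeric in [0, 1].
#' @examples
#' broadSenseH2(1, 1, 1, 1)   # 0.25
#' broadSenseH2(3, 0, 0, 1)   # 0.75
#' @export
broadSenseH2 <- function(sigma2_g, sigma2_r = 0, sigma2_c = 0,
                         sigma2_e = 0) {
    if (any(c(sigma2_g, sigma2_r, sigma2_c, sigma2_e) < 0))
        stop("variance components must be non-negative")
    tot <- sigma2_g + sigma2_r + sigma2_c + sigma2_e
    if (tot <= 0) return(0)
    sigma2_g / tot
}

## Vectorized permutation null for balanced one-way designs: genotype
## labels are shuffled across samples, so each permutation is a random
## partition of the trait values into G groups of size r. Balanced one-way
## REML equals the truncated ANOVA estimator, computed in closed form.
.permNullBalanced <- function(y, G, r, nPerm) {
    n <- G * r
    gm <- mean(y)
    sst <- sum((y - gm)^2)
    vapply(seq_len(nPerm), function(b) {
        ym <- matrix(y[sample.int(n)], nrow = r)
        ssb <- r * sum((colMeans(ym) - gm)^2)
        msb <- ssb / (G - 1)
        msw <- (sst - ssb) / (n - G)
        sg <- max(0, (msb - msw) / r)
        if (sg + msw <= 0) 0 else sg / (sg + msw)
    }, numeric(1))
}

#' Permutation null distribution of heritability
#'
#' Approximates the null distribution of \eqn{H^2} under
#' \eqn{\sigma^2_g = 0} by shuffling genotype labels across samples while
#' the trait values and the row/column/experiment assignments stay with the
#' physical samples, refitting the variance-component model each time. The
#' significance threshold is the empirical (1 - alpha) quantile of the
#' null. For balanced designs with no row/column/experiment structure a
#' closed-form fast path is used (identical to the REML fit).
#'
#' @param y trait vector.
#' @param design design data.frame (see [fitVarianceComponents()]).
#' @param nPerm number of permutations (default 1000; 10000 gives the most
#'   stable 99th percentile and is the recommended reporting value).
#' @param alpha tail probability of the threshold (default 0.01).
#' @param seed optional integer seed for reproducible permutations.
#' @return list with `null_h2` (length `nPerm`), `threshold`, `n_perm`,
#'   `alpha`.
#' @export
permutationThreshold <- function(y, design, nPerm = 1000, alpha = 0.01,
                                 seed = NULL) {
    if (nPerm < 1 / alpha)
        warning("nPerm < 1/alpha: the ", 1 - alpha,
                " quantile is poorly resolved")
    f <- .designFactors(design)
    oneway <- is.null(f$rowf) && is.null(f$colf) && nlevels(f$expf) < 2L
    balanced <- length(unique(tabulate(as.integer(f$geno)))) == 1L
    null_h2 <- .withSeed(seed, {
        if (oneway && balanced) {
            .permNullBalanced(y, nlevels(f$geno),
                              length(y) / nlevels(f$geno), nPerm)
        } else {
            d <- as.data.frame(design)
            vapply(seq_len(nPerm), function(b) {
                d2 <- d
                d2$individual <- d$individual[sample.int(nrow(d))]
                fitVarianceComponents(y, d2)$h2
            }, numeric(1))
        }
    })
    list(null_h2 = null_h2,
         threshold = unname(stats::quantile(null_h2, 1 - alpha)),
         n_perm = nPerm, alpha = alpha)
}

#' Heritability analysis of a trait matrix
#'
#' Fits variance components for every trait (row), computes broad-sense
#' heritability and a genotype-permutation null, and flags traits whose
#' observed \eqn{H^2} strictly exceeds the null threshold. Two null modes
#' are available: `"per_trait"` builds an `nPerm`-permutation null per
#' trait; `"pooled"` spreads roughly `nPerm` permutation fits across all
#' traits and shares a single pooled null (much cheaper for genome-wide
#' matrices). Empirical p-values use (1 + #null >= observed) / (1 + #null).
#'
#' @param traits numeric matrix, traits x samples.
#' @param design design data.frame (see [fitVarianceComponents()]).
#' @param nPerm permutations (per trait, or pooled total; default 1000).
#' @param alpha threshold tail (default 0.01).
#' @param nullMode `"per_trait"` or `"pooled"`.
#' @param seed optional integer seed.
#' @return data.frame with one row per trait: variance components, `h2`,
#'   `null_threshold`, `p_perm`, `heritable`, `flag`.
#' @export
estimateHeritability <- function(traits, design, nPerm = 1000, alpha = 0.01,
                                 nullMode = c("per_trait", "pooled"),
                                 seed = NULL) {
    nullMode <- match.arg(nullMode)
    traits <- as.matrix(traits)
    ids <- rownames(traits)
    if (is.null(ids)) ids <- paste0("trait", seq_len(nrow(traits)))
    fits <- lapply(seq_len(nrow(traits)), function(i)
        fitVarianceComponents(traits[i, ], design))
    out <- data.frame(
        trait_id = ids,
        sigma2_g = vapply(fits, `[[`, 0, "sigma2_g"),
        sigma2_r = vapply(fits, `[[`, 0, "sigma2_r"),
        sigma2_c = vapply(fits, `[[`, 0, "sigma2_c"),
        sigma2_e = vapply(fits, `[[`, 0, "sigma2_e"),
        h2 = vapply(fits, `[[`, 0, "h2"),
        flag = vapply(fits, `[[`, "", "flag"), row.names = NULL)
    if (nullMode == "per_trait") {
        nulls <- lapply(seq_len(nrow(traits)), function(i)
            permutationThreshold(traits[i, ], design, nPerm, alpha,
                                 seed = if (is.null(seed)) NULL
                                        else seed + i))
        out$null_threshold <- vapply(nulls, `[[`, 0, "threshold")
        out$p_perm <- vapply(seq_len(nrow(traits)), function(i) {
            nh <- nulls[[i]]$null_h2
            (1 + sum(nh >= out$h2[i])) / (1 + length(nh))
        }, numeric(1))
    } else {
        per <- max(1L, ceiling(nPerm / nrow(traits)))
        ## the pooled null is large even though each trait contributes few
        ## permutations, so the per-trait resolution warning is moot here
        pool <- unlist(lapply(seq_len(nrow(traits)), function(i)
            suppressWarnings(
                permutationThreshold(traits[i, ], design, per, alpha,
                                     seed = if (is.null(seed)) NULL
                                            else seed + i)$null_h2)))
        thr <- unname(stats::quantile(pool, 1 - alpha))
        out$null_threshold <- thr
        out$p_perm <- vapply(out$h2, function(h)
            (1 + sum(pool >= h)) / (1 + length(pool)), numeric(1))
    }
    out$heritable <- out$h2 > out$null_threshold
    out
}

#' Select significantly heritable traits
#'
#' Keeps traits whose observed heritability strictly exceeds their null
#' threshold (an observed value equal to the threshold is dropped). Traits
#' without a matching null are excluded with a warning.
#'
#' @param h2 data.frame with `trait_id` and `h2`.
#' @param nulls data.frame with `trait_id` and `null_threshold` (for
#'   example the output of [estimateHeritability()]).
#' @return character vector of heritable trait ids.
#' @export
heritableSet <- function(h2, nulls) {
    idx <- match(h2$trait_id, nulls$trait_id)
    if (anyNA(idx)) {
        warning("traits without a permutation null excluded: ",
                paste(h2$trait_id[is.na(idx)], collapse = ", "))
    }
    ok <- !is.na(idx)
    h2$trait_id[ok][h2$h2[ok] > nulls$null_threshold[idx[ok]]]
}
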