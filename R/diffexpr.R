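#' Pool replicate libraries into a two-group contrast
#'
#' The MA-plot random-sampling test is a two-library model: replicates are
#' pooled by summation per group before testing. Pooled library totals are
#' the sums of the per-sample clean-read totals.
#'
#' @param cm a [count_matrix()].
#' @param g1,g2 group labels (numerator first: positive fold changes mean
#'   up in `g1`).
#' @return a `contrast_input` list: `feature_id`, `c1`, `c2`, `n1`, `n2`,
#'   `groups`.
#' @export
pool_contrast <- function(cm, g1, g2) {
    for (g in c(g1, g2)) {
        if (!g %in% cm$design$group)
            user_error("group '%s' not present in the design", g)
    }
    s1 <- cm$design$sample[cm$design$group == g1]
    s2 <- cm$design$sample[cm$design$group == g2]
    structure(list(feature_id = rownames(cm$counts),
                   c1 = rowSums(cm$counts[, s1, drop = FALSE]),
                   c2 = rowSums(cm$counts[, s2, drop = FALSE]),
                   n1 = sum(cm$total_clean[s1]),
                   n2 = sum(cm$total_clean[s2]),
                   groups = c(g1, g2)),
              class = "contrast_input")
}

#' MA-plot random-sampling (MARS) differential expression test
#'
#' Two pooled count libraries are compared through the conditional
#' distribution of `M = log2(c1) - log2(c2)` given
#' `A = (log2(c1) + log2(c2)) / 2`. Under random sampling of reads,
#' `E[M | A] = log2(n1 / n2)` and
#' `Var[M | A] = (1 - p) (n1 + n2) / (ln(2)^2 n1 n2 p)` with
#' `p = 2^A / sqrt(n1 n2)` (clipped to `[1e-12, 1 - 1e-12]`), giving a
#' standard normal `z` and a two-sided p-value. Features absent from both
#' groups are excluded; a zero count on one side only is replaced by 0.5
#' for the logarithms.
#'
#' @param contrast a `contrast_input` from [pool_contrast()], or a list with
#'   fields `feature_id`, `c1`, `c2`, `n1`, `n2`.
#' @return a data.frame (class `de_result`): `feature_id`, `c1`, `c2`, `M`,
#'   `A`, `mu` (`E[M|A]`), `var`, `z`, `p`, `norm_log2fc`
#'   (`M - log2(n1/n2)`), `direction` (`up` / `down` for group 1). Q-values
#'   are added by [adjust_de()].
#' @export
mars_test <- function(contrast) {
    n1 <- as.numeric(contrast$n1); n2 <- as.numeric(contrast$n2)
    if (!length(n1) || !length(n2) || is.na(n1) || is.na(n2) ||
        n1 <= 0 || n2 <= 0)
        user_error("pooled library totals n1, n2 must be positive")
    c1 <- as.numeric(contrast$c1); c2 <- as.numeric(contrast$c2)
    if (any(c1 < 0 | c2 < 0)) user_error("counts must be non-negative")
    keep <- (c1 + c2) > 0
    fid <- contrast$feature_id[keep]
    c1 <- c1[keep]; c2 <- c2[keep]
    if (!length(c1)) {
        out <- data.frame(feature_id = character(), c1 = numeric(),
                          c2 = numeric(), M = numeric(), A = numeric(),
                          mu = numeric(), var = numeric(), z = numeric(),
                          p = numeric(), norm_log2fc = numeric(),
                          direction = character(), stringsAsFactors = FALSE)
        class(out) <- c("de_result", "data.frame")
        return(out)
    }
    l1 <- log2(ifelse(c1 == 0, 0.5, c1))
    l2 <- log2(ifelse(c2 == 0, 0.5, c2))
    M <- l1 - l2
    A <- (l1 + l2) / 2
    eps <- 1e-12
    phat <- pmin(pmax(2^A / sqrt(n1 * n2), eps), 1 - eps)
    mu <- log2(n1 / n2)
    v <- (1 - phat) * (n1 + n2) / (log(2)^2 * n1 * n2 * phat)
    z <- (M - mu) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    nlfc <- M - mu
    out <- data.frame(feature_id = fid, c1 = c1, c2 = c2, M = M, A = A,
                      mu = mu, var = v, z = z, p = p, norm_log2fc = nlfc,
                      direction = ifelse(nlfc > 0, "up", "down"),
                      stringsAsFactors = FALSE)
    class(out) <- c("de_result", "data.frame")
    attr(out, "groups") <- contrast$groups
    out
}

#' Benjamini-Hochberg q-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1 and mapped back to the
#' input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values in input order.
#' @export
adjust_bh <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
        user_error("p-values must lie in [0, 1]")
    m <- length(p)
    if (m == 0) return(numeric())
    o <- order(p)
    # pmax guards the q >= p invariant against one-ulp rounding in p*m/m
    q <- pmin(1, pmax(p[o], rev(cummin(rev(p[o] * m / seq_len(m))))))
    q[order(o)]
}

#' Storey q-values with a fixed lambda
#'
#' Estimates the null proportion as
#' `pi0 = min(1, #\{p_i > lambda\} / ((1 - lambda) m))`, floored at `1/m`
#' when the estimate is zero, and multiplies the BH step-up quantities by
#' `pi0`.
#'
#' @param p vector of p-values.
#' @param lambda tuning point in (0, 1); a single fixed value (default 0.5)
#'   rather than spline smoothing keeps the estimator deterministic.
#' @return list with `q` (q-values in input order) and `pi0`.
#' @export
adjust_storey <- function(p, lambda = 0.5) {
    m <- length(p)
    if (m == 0) user_error("empty p-value vector")
    if (lambda <= 0 || lambda >= 1) user_error("lambda must lie in (0, 1)")
    if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
        user_error("p-values must lie in [0, 1]")
    pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
    pi0 <- max(pi0, 1 / m)
    o <- order(p)
    q <- pmin(1, rev(cummin(rev(pi0 * p[o] * m / seq_len(m)))))
    list(q = q[order(o)], pi0 = pi0)
}

#' Attach both q-value adjustments to a MARS result
#'
#' @param res a `de_result` from [mars_test()].
#' @param lambda passed to [adjust_storey()].
#' @return the result with `q_bh`, `q_storey` columns and a `pi0` attribute.
#' @export
adjust_de <- function(res, lambda = 0.5) {
    if (nrow(res)) {
        res$q_bh <- adjust_bh(res$p)
        st <- adjust_storey(res$p, lambda)
        res$q_storey <- st$q
        attr(res, "pi0") <- st$pi0
    } else {
        res$q_bh <- numeric()
        res$q_storey <- numeric()
    }
    res
}

#' Call differentially expressed features
#'
#' A feature is DE when its gated q-value is `<=` the threshold (inclusive).
#' The default gate is BH, the stricter of the two adjustments (Storey
#' q-values are never larger since `pi0 <= 1`).
#'
#' @param res an adjusted `de_result` (see [adjust_de()]).
#' @param q_threshold inclusive q-value cutoff (default 0.05).
#' @param gate `"bh"` or `"storey"`.
#' @return a `contrast_sets` list: `up`, `down` (feature ids, group-1-up
#'   means positive normalised log2 fold change), `universe` (all tested
#'   ids) and `lfc` (named normalised log2 fold changes).
#' @export
call_de <- function(res, q_threshold = 0.05, gate = c("bh", "storey")) {
    gate <- match.arg(gate)
    qcol <- paste0("q_", gate)
    if (!qcol %in% names(res))
        user_error("result lacks %s; run adjust_de() first", qcol)
    de <- res[[qcol]] <= q_threshold
    structure(list(up = res$feature_id[de & res$direction == "up"],
                   down = res$feature_id[de & res$direction == "down"],
                   universe = res$feature_id,
                   lfc = setNames(res$norm_log2fc, res$feature_id)),
              class = "contrast_sets")
}

#' One-call differential expression for a contrast
#'
#' Convenience wrapper: subset to a feature class, pool replicates, run the
#' MARS test, adjust, and call DE sets.
#'
#' @param cm a [count_matrix()].
#' @param contrast 2-vector `c(group1, group2)` or a string `"G1:G2"`.
#' @param class optional feature class to restrict to (e.g. `"pirna"`).
#' @param q_threshold,gate passed to [call_de()].
#' @return list with `result` (adjusted `de_result`) and `sets`
#'   (`contrast_sets`).
#' @export
de_analysis <- function(cm, contrast, class = NULL, q_threshold = 0.05,
                        gate = "bh") {
    if (is.character(contrast) && length(contrast) == 1L)
        contrast <- strsplit(contrast, ":", fixed = TRUE)[[1]]
    if (length(contrast) != 2L)
        user_error("contrast must name two groups, e.g. 'CS:SS'")
    if (!is.null(class)) cm <- subset_class(cm, class)
    res <- adjust_de(mars_test(pool_contrast(cm, contrast[1], contrast[2])))
    list(result = res, sets = call_de(res, q_threshold, gate))
}
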