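#' Configuration for the synthetic GWAS generator
#'
#' Bundles the generating parameters of the synthetic study design: a block-LD
#' haplotype panel, an LD-score-regression-style variance model for the
#' association z-scores (`E[chisq_j] = c + N * h2 * l_j / M`), and a pair of
#' overlapping case-control studies of different effective sample sizes over a
#' shared variant set.
#'
#' Defaults describe the study conditions emulated throughout the package: a
#' genome of 22 chromosomes of block-structured common variation, strong
#' within-block LD (adjacent haplotype correlation 0.9), a U-shaped MAF
#' spectrum floored at 0.5% (mirroring the MAF >= 0.5% filters of large
#' meta-analyses), a substantially heritable polygenic trait (h2 = 0.4 spread
#' over 10% causal variants), mild confounding in the earlier study
#' (c = 1.2) and a later study four times its effective size.
#'
#' @param m_variants Total variant count across chromosomes.
#' @param n_chromosomes Number of chromosomes (labelled "1", "2", ...).
#' @param block_size Variants per LD block.
#' @param rho Within-block adjacent-variant haplotype correlation in `[0, 1)`.
#'   A scalar fixes one correlation for every block; a length-2 vector
#'   `c(lo, hi)` draws each block's correlation uniformly from that range,
#'   emulating the heterogeneous LD strength of a real genome (recombination
#'   hotspots next to long haplotype blocks) and spreading LD scores from ~1
#'   up to `(1 + hi^2) / (1 - hi^2)`.
#' @param n_hap Number of haplotypes in the reference panel.
#' @param maf_shape Length-2 beta shape pair for the MAF spectrum.
#' @param maf_floor Lower bound of the MAF spectrum (default 0.5%).
#' @param h2 Trait heritability in `[0, 1)`.
#' @param prop_causal Fraction of causal variants in `(0, 1]`.
#' @param c_earlier,c_later Confounding intercepts (>= 1) of the two studies.
#' @param n_earlier,n_later Effective sample sizes of the two studies. The
#'   defaults are scaled to the default variant count so the per-variant
#'   polygenic signal `N * h2 / M` sits in the regime of real large
#'   meta-analyses (inflation factors around 1.3-1.6, mean chi-square near
#'   2), with the later study four times the earlier one.
#' @param overlap Correlation of the study-specific noise terms induced by
#'   sample overlap (default 0 = independent noise).
#' @param maf_power Scale each variant's polygenic non-centrality by
#'   `2 * maf * (1 - maf)` (normalised to unit mean), the additive-coding
#'   genotype variance, so that low-MAF variants carry less power. Off by
#'   default: the baseline generator is the exact LDSR variance form, which
#'   is what the estimators assume; enable this to study MAF-dependent
#'   power (e.g. the lambda-by-MAF-threshold profile).
#' @param window_kb LD-score window radius in kb.
#' @param seed Integer seed from which all randomness flows.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(m_variants = 20000,
                         n_chromosomes = 22,
                         block_size = 50,
                         rho = c(0, 0.9),
                         n_hap = 500,
                         maf_shape = c(0.5, 0.5),
                         maf_floor = 0.005,
                         h2 = 0.4,
                         prop_causal = 0.3,
                         c_earlier = 1.2,
                         c_later = 1.1,
                         n_earlier = 20000,
                         n_later = 80000,
                         overlap = 0,
                         maf_power = FALSE,
                         window_kb = 1000,
                         seed = 1L) {
  cfg <- list(
    m_variants = as.integer(m_variants),
    n_chromosomes = as.integer(n_chromosomes),
    block_size = as.integer(block_size),
    rho = rho, n_hap = as.integer(n_hap),
    maf_shape = maf_shape, maf_floor = maf_floor,
    h2 = h2, prop_causal = prop_causal,
    c_earlier = c_earlier, c_later = c_later,
    n_earlier = n_earlier, n_later = n_later,
    overlap = overlap, maf_power = maf_power,
    window_kb = window_kb, seed = as.integer(seed)
  )
  if (any(cfg$rho < 0) || any(cfg$rho >= 1)) {
    stop("`rho` must be in [0, 1)", call. = FALSE)
  }
  if (!length(cfg$rho) %in% 1:2) {
    stop("`rho` must be a scalar or a length-2 range", call. = FALSE)
  }
  if (cfg$h2 < 0 || cfg$h2 >= 1) stop("`h2` must be in [0, 1)", call. = FALSE)
  if (cfg$prop_causal <= 0 || cfg$prop_causal > 1) {
    stop("`prop_causal` must be in (0, 1]", call. = FALSE)
  }
  if (cfg$c_earlier < 1 || cfg$c_later < 1) {
    stop("confounding intercepts must be >= 1", call. = FALSE)
  }
  if (cfg$maf_floor <= 0 || cfg$maf_floor >= 0.5) {
    stop("`maf_floor` must be in (0, 0.5)", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

.maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Simulate a block-LD haplotype reference panel
#'
#' Builds per-chromosome 0/1 haplotype matrices with block-diagonal LD.
#' Within a block every variant shares one MAF drawn from the configured
#' spectrum and alleles follow a copy-with-refresh Markov chain: each
#' haplotype copies its allele from the previous variant with probability
#' `rho`, else redraws a fresh Bernoulli(freq) allele. For equal-frequency
#' binary alleles this gives adjacent-variant correlation exactly `rho`
#' (AR(1)-like decay `rho^d` at lag `d`); across blocks variants are
#' independent. Positions place each block well inside a 500 kb window with
#' > 1 Mb gaps between blocks. Columns drawn monomorphic at low MAF are made
#' polymorphic by flipping a single haplotype.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return A list of class `ld_panel`: `variants` tibble (`chrom`, `pos`,
#'   `id`, `ea`, `oa`, `block`, `eaf_model`, `eaf`, `maf`), per-chromosome
#'   `haplotypes` matrices (n_hap x variants), and `n_hap`.
#' @export
simulate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (any(config$rho >= 1)) stop("`rho` must be < 1", call. = FALSE)
  .maybe_seed(seed)
  rho_range <- range(config$rho)

  m <- config$m_variants
  n_chr <- config$n_chromosomes
  bs <- config$block_size
  n_hap <- config$n_hap
  m_chr <- rep(m %/% n_chr, n_chr)
  extra <- m - sum(m_chr)
  if (extra > 0) m_chr[seq_len(extra)] <- m_chr[seq_len(extra)] + 1L

  allele_pairs <- c("A", "C", "G", "T")
  haplotypes <- vector("list", n_chr)
  var_rows <- vector("list", n_chr)
  gid <- 0L
  for (ci in seq_len(n_chr)) {
    mc <- m_chr[ci]
    n_blocks <- ceiling(mc / bs)
    H <- matrix(0L, nrow = n_hap, ncol = mc)
    pos <- integer(mc)
    block_id <- integer(mc)
    eaf_model <- numeric(mc)
    col <- 0L
    for (b in seq_len(n_blocks)) {
      len <- min(bs, mc - col)
      maf <- config$maf_floor +
        (0.5 - config$maf_floor) * stats::rbeta(1, config$maf_shape[1], config$maf_shape[2])
      f <- if (stats::runif(1) < 0.5) maf else 1 - maf
      rho_b <- stats::runif(1, rho_range[1], rho_range[2])
      h <- matrix(0L, nrow = n_hap, ncol = len)
      h[, 1] <- stats::rbinom(n_hap, 1L, f)
      if (len > 1) {
        for (j in 2:len) {
          copy <- stats::runif(n_hap) < rho_b
          fresh <- stats::rbinom(n_hap, 1L, f)
          h[, j] <- ifelse(copy, h[, j - 1], fresh)
        }
      }
      # guarantee polymorphism (needed for correlations / LD scores)
      cs <- colSums(h)
      for (j in which(cs == 0L)) h[sample.int(n_hap, 1), j] <- 1L
      for (j in which(cs == n_hap)) h[sample.int(n_hap, 1), j] <- 0L
      idx <- col + seq_len(len)
      H[, idx] <- h
      # block span ~ (block_size * 100) bp << 500 kb; inter-block gap 2 Mb
      pos[idx] <- 1000000L + (b - 1L) * 2000000L + (seq_len(len) - 1L) * 100L
      block_id[idx] <- b
      eaf_model[idx] <- f
      col <- col + len
    }
    al <- t(vapply(
      seq_len(mc),
      function(i) sample(allele_pairs, 2L),
      character(2)
    ))
    var_rows[[ci]] <- tibble::tibble(
      chrom = as.character(ci),
      pos = pos,
      id = paste0("rs", gid + seq_len(mc)),
      ea = al[, 1], oa = al[, 2],
      block = block_id,
      eaf_model = eaf_model,
      eaf = colMeans(H)
    )
    gid <- gid + mc
    haplotypes[[ci]] <- H
  }
  variants <- dplyr::bind_rows(var_rows)
  variants$maf <- pmin(variants$eaf, 1 - variants$eaf)
  names(haplotypes) <- as.character(seq_len(n_chr))
  structure(
    list(
      variants = variants, haplotypes = haplotypes,
      n_hap = n_hap, config = config
    ),
    class = "ld_panel"
  )
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(
    "<ld_panel> ", nrow(x$variants), " variants, ",
    length(x$haplotypes), " chromosomes, ", x$n_hap, " haplotypes\n",
    sep = ""
  )
  invisible(x)
}

# per-variant MAF-power modulation, normalised to mean 1
.maf_modulation <- function(eaf, enabled) {
  if (!enabled) {
    return(rep(1, length(eaf)))
  }
  w <- 2 * eaf * (1 - eaf)
  w / mean(w)
}

# build a summary-statistics tibble from z-scores over the panel variant set
.zscores_to_sumstats <- function(panel, z, n) {
  v <- panel$variants
  se <- 1 / sqrt(2 * v$eaf * (1 - v$eaf) * n)
  chisq <- z^2
  tibble::tibble(
    chrom = v$chrom, pos = v$pos, id = v$id, ea = v$ea, oa = v$oa,
    eaf = v$eaf, maf = v$maf,
    beta = z * se, se = se,
    neg_log10_p = chisq_to_p(chisq), chisq = chisq,
    n = rep(n, nrow(v))
  )
}

#' Simulate GWAS summary statistics over a panel
#'
#' Draws per-variant z-scores under the LD-score-regression variance model:
#' `z_j ~ N(0, sqrt(c + N * h2 * l_j / M))` (null-polygenic form), optionally
#' modulated by the additive-coding MAF power factor; `chisq = z^2`, betas
#' carry the sign of z with `se = 1 / sqrt(2 * eaf * (1 - eaf) * N)`, and
#' effect-allele frequencies come from the panel. When shared true effects are
#' supplied (from [simulate_study_pair()]'s truth), z is instead
#' `sqrt(N) * effect + noise` with noise variance `c`.
#'
#' @param panel An [simulate_panel()] object.
#' @param n Effective sample size.
#' @param c Confounding intercept (>= 1); the expected chi-square of a variant
#'   with no polygenic signal.
#' @param h2 Heritability (ignored when `effects` is given).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param scores Optional precomputed LD scores (tibble with `id`, `l2`);
#'   computed from the panel when needed and absent.
#' @param effects Optional per-variant true effect vector (standardised
#'   scale), aligned to `panel$variants`.
#' @param maf_power Apply the MAF power modulation (default from the panel's
#'   config).
#' @return A summary-statistics tibble; attribute `params` records `c`, `n`,
#'   `h2`.
#' @export
simulate_sumstats <- function(panel, n, c, h2 = 0, seed = NULL,
                              scores = NULL, effects = NULL,
                              maf_power = panel$config$maf_power) {
  stopifnot(inherits(panel, "ld_panel"))
  if (c < 1) stop("confounding intercept `c` must be >= 1", call. = FALSE)
  .maybe_seed(seed)
  v <- panel$variants
  m <- nrow(v)
  if (!is.null(effects)) {
    stopifnot(length(effects) == m)
    z <- sqrt(n) * effects + stats::rnorm(m, sd = sqrt(c))
  } else if (h2 > 0) {
    if (is.null(scores)) {
      scores <- compute_ld_scores(panel, window_kb = panel$config$window_kb)
    }
    l2 <- scores$l2[match(v$id, scores$id)]
    mod <- .maf_modulation(v$eaf, maf_power)
    vj <- c + n * h2 * l2 * mod / m
    z <- stats::rnorm(m, sd = sqrt(vj))
  } else {
    z <- stats::rnorm(m, sd = sqrt(c))
  }
  out <- .zscores_to_sumstats(panel, z, n)
  attr(out, "params") <- list(c = c, n = n, h2 = h2)
  out
}

#' Simulate an overlapping earlier/later study pair with known truth
#'
#' Generates one haplotype panel, one set of shared true effects (causal
#' variants drawn at rate `prop_causal`, effect variance proportional to
#' `h2 * l_j / M` so the LDSR expectation holds marginally), and two studies
#' over the same variant set: `z_s = sqrt(N_s) * effect + noise_s` with
#' study-specific confounding variance `c_s`. Noise is independent between
#' studies by default; `overlap` sets its correlation.
#'
#' @param config A [synth_config()].
#' @return A list with `earlier` and `later` summary-statistics tibbles and
#'   `truth`, a `synth_truth` list carrying per-variant causal flags and
#'   effects, the generating parameters, the LD scores and the panel.
#' @export
simulate_study_pair <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  panel <- simulate_panel(config, seed = NULL)
  scores <- compute_ld_scores(panel, window_kb = config$window_kb)
  v <- panel$variants
  m <- nrow(v)
  l2 <- scores$l2[match(v$id, scores$id)]
  mod <- .maf_modulation(v$eaf, config$maf_power)

  causal <- stats::runif(m) < config$prop_causal
  eff_var <- config$h2 * l2 * mod / (m * config$prop_causal)
  effects <- ifelse(causal, stats::rnorm(m, sd = sqrt(eff_var)), 0)

  eps_e <- stats::rnorm(m)
  eps_i <- stats::rnorm(m)
  r <- config$overlap
  eps_l <- r * eps_e + sqrt(1 - r^2) * eps_i
  z_e <- sqrt(config$n_earlier) * effects + sqrt(config$c_earlier) * eps_e
  z_l <- sqrt(config$n_later) * effects + sqrt(config$c_later) * eps_l

  earlier <- .zscores_to_sumstats(panel, z_e, config$n_earlier)
  later <- .zscores_to_sumstats(panel, z_l, config$n_later)
  attr(earlier, "params") <- list(
    c = config$c_earlier, n = config$n_earlier, h2 = config$h2
  )
  attr(later, "params") <- list(
    c = config$c_later, n = config$n_later, h2 = config$h2
  )
  truth <- structure(
    list(
      variants = tibble::tibble(
        chrom = v$chrom, pos = v$pos, id = v$id,
        causal = causal, effect = effects
      ),
      params = config,
      scores = scores,
      panel = panel
    ),
    class = "synth_truth"
  )
  list(earlier = earlier, later = later, truth = truth)
}

#' Derive study-defined index variants from simulated statistics
#'
#' Stand-in for the published lead-variant lists of real studies: returns the
#' index variants of [greedy_clump()] on the given statistics at default
#' thresholds.
#'
#' @param stats A summary-statistics tibble.
#' @param ld An LD provider ([simulate_panel()] object or pairwise r2 table,
#'   see [greedy_clump()]).
#' @param ... Passed to [greedy_clump()].
#' @return A tibble of index variants (`chrom`, `pos`, `id`, `ea`, `oa`);
#'   empty when nothing reaches the index threshold.
#' @export
make_index_variants <- function(stats, ld, ...) {
  clumps <- greedy_clump(stats, ld, ...)
  if (nrow(clumps) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), id = character(),
      ea = character(), oa = character()
    ))
  }
  key <- dplyr::select(
    stats, "chrom", "pos", "id",
    dplyr::any_of(c("ea", "oa"))
  )
  dplyr::inner_join(
    tibble::tibble(chrom = clumps$chrom, pos = clumps$index_pos, id = clumps$index_id),
    key,
    by = c("chrom", "pos", "id")
  )
}
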