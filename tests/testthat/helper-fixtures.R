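# Shared fixtures for the test suite. Everything is generated in code; the
# heavier shared objects (a mid-size panel with LD scores) are built lazily
# and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# mid-size panel at the parameter-recovery study conditions (M = 20,000)
shared_panel <- function() {
  if (is.null(.fixture_env$panel)) {
    cfg <- synth_config(m_variants = 20000, n_chromosomes = 22, seed = 7101)
    .fixture_env$panel <- simulate_panel(cfg, seed = 7101)
    .fixture_env$scores <- compute_ld_scores(.fixture_env$panel)
  }
  .fixture_env$panel
}
shared_scores <- function() {
  shared_panel()
  .fixture_env$scores
}

# hand-built summary-statistics tibble; p given as -log10
make_stats <- function(nlp,
                       chrom = rep("1", length(nlp)),
                       pos = seq_along(nlp) * 1000L,
                       beta = rep(0.1, length(nlp)),
                       eaf = rep(0.3, length(nlp)),
                       id = paste0("rs", seq_along(nlp)),
                       ea = rep("A", length(nlp)),
                       oa = rep("G", length(nlp)),
                       n = NULL) {
  out <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), id = id, ea = ea, oa = oa,
    eaf = eaf, maf = pmin(eaf, 1 - eaf),
    beta = beta, se = rep(0.02, length(nlp)),
    neg_log10_p = nlp, chisq = p_to_chisq(nlp)
  )
  if (!is.null(n)) out$n <- n
  out
}

# manual LD panel from an explicit haplotype matrix (one chromosome)
make_manual_panel <- function(H, pos, chrom = "1") {
  m <- ncol(H)
  variants <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), id = paste0("rs", seq_len(m)),
    ea = "A", oa = "G", block = 1L,
    eaf_model = colMeans(H), eaf = colMeans(H)
  )
  variants$maf <- pmin(variants$eaf, 1 - variants$eaf)
  structure(
    list(
      variants = variants,
      haplotypes = stats::setNames(list(H), chrom),
      n_hap = nrow(H),
      config = synth_config()
    ),
    class = "ld_panel"
  )
}

# independent reference implementation of the greedy clumping rule:
# full exhaustive rescan of the candidate table at every step
reference_clump <- function(stats, r2_table, p_index = 5e-8, p_secondary = 5e-6,
                            r2_min = 0.20, window_kb = 500) {
  thr_i <- -log10(p_index)
  thr_s <- -log10(p_secondary)
  known <- union(r2_table$id_a, r2_table$id_b)
  r2_of <- function(a, b) {
    if (a == b) {
      return(1)
    }
    hit <- r2_table$r2[(r2_table$id_a == a & r2_table$id_b == b) |
      (r2_table$id_a == b & r2_table$id_b == a)]
    if (length(hit)) hit[1] else 0
  }
  cand <- stats[stats$neg_log10_p >= thr_s, , drop = FALSE]
  cand$assigned <- FALSE
  clumps <- list()
  repeat {
    pool <- which(!cand$assigned & cand$neg_log10_p >= thr_i)
    if (!length(pool)) break
    chrom_rank <- suppressWarnings(as.integer(cand$chrom[pool]))
    chrom_rank[is.na(chrom_rank)] <- 23L
    ord <- pool[order(-cand$neg_log10_p[pool], chrom_rank, cand$pos[pool])]
    i <- ord[1]
    if (!cand$id[i] %in% known) {
      members <- i
    } else {
      members <- i
      for (j in which(!cand$assigned)) {
        if (j == i) next
        if (cand$chrom[j] != cand$chrom[i]) next
        if (abs(cand$pos[j] - cand$pos[i]) > window_kb * 1000) next
        if (!cand$id[j] %in% known) next
        if (r2_of(cand$id[i], cand$id[j]) >= r2_min) members <- c(members, j)
      }
    }
    cand$assigned[members] <- TRUE
    clumps[[length(clumps) + 1]] <- list(
      index = cand$id[i], members = sort(cand$id[members])
    )
    if (all(cand$assigned | cand$neg_log10_p < thr_i)) next
  }
  clumps
}

# random clumping instance over an r2-table LD provider
random_instance <- function(m = 20) {
  chrom <- as.character(sample(1:2, m, replace = TRUE))
  pos <- sample.int(2e6, m)
  nlp <- runif(m, 4, 12) # spans secondary and index thresholds
  ids <- paste0("v", seq_len(m))
  stats <- make_stats(nlp = nlp, chrom = chrom, pos = pos, id = ids)
  # random sparse symmetric r2 table; some variants absent from the provider
  known <- sample(ids, size = max(2, round(0.8 * m)))
  pairs <- t(combn(known, 2))
  keep <- runif(nrow(pairs)) < 0.4
  r2 <- tibble::tibble(
    id_a = pairs[keep, 1], id_b = pairs[keep, 2],
    r2 = runif(sum(keep))
  )
  # ensure every known id appears even with no retained pair
  if (!all(known %in% c(r2$id_a, r2$id_b))) {
    miss <- setdiff(known, c(r2$id_a, r2$id_b))
    anchor <- setdiff(known, miss)[1]
    r2 <- dplyr::bind_rows(
      r2,
      tibble::tibble(id_a = miss, id_b = anchor, r2 = 0)
    )
  }
  list(stats = stats, r2 = r2)
}

clump_signature <- function(clumps) {
  sig <- purrr::map(clumps$members, function(m) sort(m$id))
  sig[order(clumps$index_id)]
}
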