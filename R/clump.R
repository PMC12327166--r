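.chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.integer(chrom))
  r[is.na(r) & chrom == "X"] <- 23L
  r[is.na(r)] <- 24L
  r
}

# LD provider abstraction: either a haplotype panel or a precomputed pairwise
# r2 table (columns id_a, id_b, r2; symmetric lookup, self r2 = 1, listed
# variants with no entry for a pair have r2 = 0). Returns closures:
#   known(ids)                -> logical, variant is present in the provider
#   r2(chrom, id, other_ids)  -> numeric vector of r2 with the index variant
.ld_provider <- function(ld) {
  if (inherits(ld, "ld_panel")) {
    v <- ld$variants
    list(
      known = function(ids) ids %in% v$id,
      r2 = function(chrom, id, other_ids) {
        vc <- v[v$chrom == chrom, , drop = FALSE]
        H <- ld$haplotypes[[chrom]]
        i <- match(id, vc$id)
        j <- match(other_ids, vc$id)
        out <- rep(NA_real_, length(other_ids))
        ok <- !is.na(j)
        if (any(ok)) {
          out[ok] <- as.numeric(stats::cor(H[, i], H[, j[ok], drop = FALSE]))^2
        }
        out
      }
    )
  } else if (is.data.frame(ld)) {
    stopifnot(all(c("id_a", "id_b", "r2") %in% names(ld)))
    ids <- union(ld$id_a, ld$id_b)
    tab <- c(
      stats::setNames(ld$r2, paste(ld$id_a, ld$id_b, sep = "\r")),
      stats::setNames(ld$r2, paste(ld$id_b, ld$id_a, sep = "\r"))
    )
    list(
      known = function(x) x %in% ids,
      r2 = function(chrom, id, other_ids) {
        out <- unname(tab[paste(id, other_ids, sep = "\r")])
        out[other_ids == id] <- 1
        out[is.na(out) & other_ids %in% ids] <- 0
        out
      }
    )
  } else {
    stop("`ld` must be an ld_panel or a data frame with id_a, id_b, r2",
      call. = FALSE
    )
  }
}

#' Greedy LD clumping (PLINK-style)
#'
#' Iteratively takes the unassigned variant with the smallest p-value among
#' those reaching the index threshold, and assigns to its clump every
#' unassigned variant reaching the secondary threshold that lies within
#' `window_kb` of the index (radius convention) on the same chromosome and
#' has `r2 >= r2_min` with it. Ties on p between index candidates are broken
#' by (chromosome, position) ascending, so the output is invariant to input
#' row order. Index candidates absent from the LD provider become
#' single-variant clumps flagged `ld_absent`.
#'
#' @param stats Summary-statistics tibble (`chrom`, `pos`, `id`,
#'   `neg_log10_p`).
#' @param ld LD provider: an [simulate_panel()] object or a pairwise table
#'   with columns `id_a`, `id_b`, `r2`.
#' @param p_index Index significance threshold (default 5e-8).
#' @param p_secondary Secondary threshold for clump membership (default
#'   5e-6).
#' @param r2_min Minimum r2 with the index variant (default 0.20).
#' @param window_kb Window radius around the index in kb (default 500).
#' @return A tibble with one row per clump: `clump_id`, `chrom`, `index_id`,
#'   `index_pos`, `index_nlp`, `n_members`, `bound_lo`, `bound_hi`,
#'   `ld_absent`, and a `members` list-column of member tibbles (`chrom`,
#'   `pos`, `id`, `neg_log10_p`). Empty (zero rows) when nothing reaches the
#'   index threshold.
#' @export
greedy_clump <- function(stats, ld, p_index = 5e-8, p_secondary = 5e-6,
                         r2_min = 0.20, window_kb = 500) {
  prov <- .ld_provider(ld)
  thr_idx <- .nlp_threshold(p_index)
  thr_sec <- .nlp_threshold(p_secondary)
  window <- window_kb * 1000

  cand <- stats[stats$neg_log10_p >= thr_sec, c("chrom", "pos", "id", "neg_log10_p")]
  cand <- cand[order(-cand$neg_log10_p, .chrom_rank(cand$chrom), cand$pos), , drop = FALSE]
  cand$known <- prov$known(cand$id)
  assigned <- rep(FALSE, nrow(cand))

  clumps <- list()
  repeat {
    i <- which(!assigned & cand$neg_log10_p >= thr_idx)[1]
    if (is.na(i)) break
    if (!cand$known[i]) {
      members <- cand[i, c("chrom", "pos", "id", "neg_log10_p")]
      assigned[i] <- TRUE
      ld_absent <- TRUE
    } else {
      near <- which(
        !assigned & cand$chrom == cand$chrom[i] &
          abs(cand$pos - cand$pos[i]) <= window & cand$known
      )
      r2 <- prov$r2(cand$chrom[i], cand$id[i], cand$id[near])
      take <- near[!is.na(r2) & r2 >= r2_min]
      take <- union(i, take)
      members <- cand[take, c("chrom", "pos", "id", "neg_log10_p")]
      assigned[take] <- TRUE
      ld_absent <- FALSE
    }
    clumps[[length(clumps) + 1]] <- tibble::tibble(
      chrom = cand$chrom[i],
      index_id = cand$id[i],
      index_pos = cand$pos[i],
      index_nlp = cand$neg_log10_p[i],
      n_members = nrow(members),
      bound_lo = min(members$pos),
      bound_hi = max(members$pos),
      ld_absent = ld_absent,
      members = list(members)
    )
  }
  if (length(clumps) == 0) {
    return(tibble::tibble(
      clump_id = integer(), chrom = character(), index_id = character(),
      index_pos = integer(), index_nlp = numeric(), n_members = integer(),
      bound_lo = integer(), bound_hi = integer(), ld_absent = logical(),
      members = list()
    ))
  }
  out <- dplyr::bind_rows(clumps)
  dplyr::bind_cols(tibble::tibble(clump_id = seq_len(nrow(out))), out)
}

#' Genomic boundaries of clumps
#'
#' Recomputes each clump's boundaries as the minimum and maximum genomic
#' position over its members.
#'
#' @param clumps A [greedy_clump()] tibble.
#' @return A tibble with `clump_id`, `bound_lo`, `bound_hi`.
#' @export
clump_bounds <- function(clumps) {
  if (nrow(clumps) == 0) {
    return(tibble::tibble(
      clump_id = integer(), bound_lo = integer(), bound_hi = integer()
    ))
  }
  tibble::tibble(
    clump_id = clumps$clump_id,
    bound_lo = vapply(clumps$members, function(m) min(m$pos), numeric(1)),
    bound_hi = vapply(clumps$members, function(m) max(m$pos), numeric(1))
  )
}

# long membership table: one row per (clump_id, member variant)
.clump_membership <- function(clumps) {
  if (nrow(clumps) == 0) {
    return(tibble::tibble(
      clump_id = integer(), chrom = character(), pos = integer(),
      id = character(), neg_log10_p = numeric()
    ))
  }
  tidyr::unnest(
    dplyr::select(clumps, "clump_id", "members"),
    "members"
  )
}

#' Tag clumps containing study-defined index variants
#'
#' A clump is tagged if and only if a study index variant is one of its
#' members (membership, not boundary overlap; an index variant absent from
#' the clumped variant set does not tag by proximity). Index variants falling
#' in no clump are reported separately.
#'
#' @param index_variants Tibble of index variants with `chrom`, `pos`.
#' @param clumps A [greedy_clump()] tibble.
#' @return A list: `tags`, the clump table with a logical `tagged` column;
#'   `unplaced`, the index variants matching no clump member.
#' @export
map_index_to_clumps <- function(index_variants, clumps) {
  mem <- .clump_membership(clumps)
  hit <- dplyr::inner_join(
    dplyr::select(index_variants, "chrom", "pos"),
    dplyr::select(mem, "clump_id", "chrom", "pos"),
    by = c("chrom", "pos")
  )
  tags <- clumps
  tags$tagged <- clumps$clump_id %in% hit$clump_id
  placed <- paste(hit$chrom, hit$pos)
  unplaced <- index_variants[
    !paste(index_variants$chrom, index_variants$pos) %in% placed, ,
    drop = FALSE
  ]
  list(tags = tags, unplaced = unplaced)
}

#' Independent-loci loss report
#'
#' Accounts for how many independent loci the lost robust associations
#' represent. Lost robust associations inside the MHC interval are removed
#' first (its extreme LD defeats locus assignment); those falling in
#' single-variant clumps formed from LD-provider-absent variants (or in no
#' clump at all) are excluded; the remainder are mapped to their clumps, and
#' the unique clumps untagged by any study index variant are the lost
#' independent loci. The loss percentage uses the before-correction denominator:
#' lost loci plus loci identified in the smaller study.
#'
#' @param lost_robust Tibble of lost robust associations (`chrom`, `pos`).
#' @param clumps A [greedy_clump()] tibble.
#' @param tagging Output of [map_index_to_clumps()].
#' @param n_loci_identified Independent loci identified in the smaller study
#'   (external input, e.g. the published locus count).
#' @param mhc MHC exclusion interval as `list(chrom, lo, hi)`; defaults to
#'   the GRCh37 interval chr6:28,477,797-33,448,354.
#' @return A one-row tibble: `n_loci_identified`, `n_mhc_excluded`,
#'   `n_single_excluded`, `n_lost_robust_untagged`, `n_lost_loci`,
#'   `pct_lost` (`NA` when both numerator terms are zero).
#' @export
lost_loci_report <- function(lost_robust, clumps, tagging, n_loci_identified,
                             mhc = list(chrom = "6", lo = 28477797, hi = 33448354)) {
  in_mhc <- lost_robust$chrom == mhc$chrom &
    lost_robust$pos >= mhc$lo & lost_robust$pos <= mhc$hi
  n_mhc <- sum(in_mhc)
  lost <- lost_robust[!in_mhc, , drop = FALSE]

  mem <- .clump_membership(clumps)
  mapped <- dplyr::left_join(
    dplyr::select(lost, "chrom", "pos"),
    dplyr::select(mem, "clump_id", "chrom", "pos"),
    by = c("chrom", "pos")
  )
  absent_ids <- clumps$clump_id[clumps$ld_absent]
  single <- is.na(mapped$clump_id) | mapped$clump_id %in% absent_ids
  n_single <- sum(single)
  mapped <- mapped[!single, , drop = FALSE]

  tagged_ids <- tagging$tags$clump_id[tagging$tags$tagged]
  untagged <- mapped[!mapped$clump_id %in% tagged_ids, , drop = FALSE]
  n_untagged <- nrow(untagged)
  n_lost_loci <- dplyr::n_distinct(untagged$clump_id)

  pct <- if (n_lost_loci + n_loci_identified > 0) {
    percent_lost_loci(n_lost_loci, n_loci_identified)
  } else {
    NA_real_
  }
  tibble::tibble(
    n_loci_identified = n_loci_identified,
    n_mhc_excluded = n_mhc,
    n_single_excluded = n_single,
    n_lost_robust_untagged = n_untagged,
    n_lost_loci = n_lost_loci,
    pct_lost = pct
  )
}

#' Percentage of lost independent loci
#'
#' `100 * n_lost / (n_lost + n_identified)`: the loci lost to correction over
#' the total independent loci before correction (lost plus identified in the
#' smaller study).
#'
#' @param n_lost Independent loci lost to correction.
#' @param n_identified Independent loci identified in the smaller study.
#' @return A percentage.
#' @export
#' @examples
#' percent_lost_loci(149, 231) # 39.2% of 380
percent_lost_loci <- function(n_lost, n_identified) {
  if (n_lost + n_identified <= 0) {
    stop("`n_lost + n_identified` must be > 0", call. = FALSE)
  }
  100 * n_lost / (n_lost + n_identified)
}
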