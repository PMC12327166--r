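#' @importFrom rlang .data
NULL

VALID_CHROMS <- c(as.character(1:22), "X")

# canonical logical -> file column names for the sumstats dialect
.sumstats_default_map <- c(
  chrom = "CHR", pos = "POS", id = "ID", ea = "EA", oa = "OA",
  eaf = "EAF", beta = "BETA", se = "SE", p = "P",
  neg_log10_p = "NEG_LOG10_P", n = "N"
)

.read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", first)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or whitespace-delimited summary-statistics file, maps its
#' columns onto the canonical layout, and validates every row. Rows failing
#' validation (p outside (0, 1], non-positive SE, allele problems, frequency
#' outside (0, 1), duplicated variant keys, ...) are dropped and counted in the
#' `drop_tally` attribute rather than raising errors. P-values are stored as
#' -log10 p together with the equivalent chi-square statistic so that
#' downstream arithmetic never underflows.
#'
#' @param path Path to a delimited text file with a header (may be gzipped).
#' @param column_map Named character vector mapping logical names (`chrom`,
#'   `pos`, `id`, `ea`, `oa`, `eaf`, `beta`, `se`, `p` or `neg_log10_p`,
#'   optionally `n`) to the actual file headers. Defaults to the canonical
#'   `CHR`, `POS`, `ID`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`/`NEG_LOG10_P`,
#'   `N` layout; partial maps override individual entries.
#' @return A validated summary-statistics tibble with columns `chrom`, `pos`,
#'   `id`, `ea`, `oa`, `eaf`, `maf`, `beta`, `se`, `neg_log10_p`, `chisq` and
#'   (if present) `n`; attribute `drop_tally` is a named integer vector of
#'   dropped-row counts by reason.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  map <- .sumstats_default_map
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- .read_delim_auto(path)

  pick <- function(logical_name) {
    col <- map[[logical_name]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NULL
  }
  mandatory <- c("chrom", "pos", "id", "ea", "oa", "eaf", "beta", "se")
  for (nm in mandatory) {
    if (is.null(pick(nm))) {
      stop("missing mandatory column `", map[[nm]], "` (", nm, ") in ", path,
        call. = FALSE
      )
    }
  }
  nlp <- pick("neg_log10_p")
  p <- pick("p")
  if (is.null(nlp) && is.null(p)) {
    stop("missing p-value column: need `", map[["p"]], "` or `",
      map[["neg_log10_p"]], "` in ", path,
      call. = FALSE
    )
  }

  # an all-T allele column is parsed as logical by delimited readers
  as_allele <- function(x) {
    x <- toupper(as.character(x))
    x[x == "TRUE"] <- "T"
    x
  }
  out <- tibble::tibble(
    chrom = as.character(pick("chrom")),
    pos = as.integer(pick("pos")),
    id = as.character(pick("id")),
    ea = as_allele(pick("ea")),
    oa = as_allele(pick("oa")),
    eaf = as.numeric(pick("eaf")),
    beta = as.numeric(pick("beta")),
    se = as.numeric(pick("se"))
  )
  if (!is.null(nlp)) {
    out$neg_log10_p <- as.numeric(nlp)
  } else {
    pv <- as.numeric(p)
    # p = 0 or p outside (0, 1] is flagged during validation via NA/negative
    out$neg_log10_p <- ifelse(is.finite(pv) & pv > 0 & pv <= 1, -log10(pv), NA_real_)
    out$neg_log10_p[is.finite(pv) & pv == 1] <- 0
  }
  nval <- pick("n")
  if (!is.null(nval)) out$n <- as.numeric(nval)

  validate_sumstats(out)
}

#' Validate (or re-validate) a summary-statistics tibble
#'
#' Applies the full row-level validation: finite fields, position >= 1,
#' chromosome in 1-22/X, distinct single-base alleles, EAF strictly inside
#' (0, 1), SE > 0, -log10 p >= 0, and uniqueness of the variant key
#' (chromosome, position, unordered allele pair) -- the second and later
#' occurrences of a duplicated key are dropped, as are multi-allelic records
#' sharing a position with a different allele pair. Derives `chisq` from
#' `neg_log10_p` when absent (and checks consistency when both are present)
#' and `maf = min(eaf, 1 - eaf)`. Validation is idempotent: re-validating a
#' validated table drops nothing.
#'
#' @param stats A data frame with at least `chrom`, `pos`, `id`, `ea`, `oa`,
#'   `eaf`, `beta`, `se`, `neg_log10_p`.
#' @return The validated tibble with attribute `drop_tally`.
#' @export
validate_sumstats <- function(stats) {
  x <- tibble::as_tibble(stats)
  tally <- c()
  note <- function(reason, keep) {
    n_drop <- sum(!keep)
    if (n_drop > 0) tally[reason] <<- n_drop
    keep
  }

  keep <- note("bad_chrom", x$chrom %in% VALID_CHROMS)
  keep <- keep & note("bad_pos", !is.na(x$pos) & x$pos >= 1L)
  keep <- keep & note(
    "bad_alleles",
    !is.na(x$ea) & !is.na(x$oa) & x$ea != x$oa &
      x$ea %in% c("A", "C", "G", "T") & x$oa %in% c("A", "C", "G", "T")
  )
  keep <- keep & note("bad_eaf", is.finite(x$eaf) & x$eaf > 0 & x$eaf < 1)
  keep <- keep & note("bad_se", is.finite(x$se) & x$se > 0)
  keep <- keep & note("bad_beta", is.finite(x$beta))
  keep <- keep & note("bad_p", is.finite(x$neg_log10_p) & x$neg_log10_p >= 0)
  x <- x[keep, , drop = FALSE]

  # variant key: chromosome, position, unordered allele pair
  akey <- paste(x$chrom, x$pos,
    pmin(x$ea, x$oa), pmax(x$ea, x$oa),
    sep = ":"
  )
  dup <- duplicated(akey)
  if (any(dup)) tally["duplicate_key"] <- sum(dup)
  x <- x[!dup, , drop = FALSE]
  # multi-allelic: same chrom:pos left with >1 distinct allele pair -> drop all
  pkey <- paste(x$chrom, x$pos, sep = ":")
  multi <- pkey %in% pkey[duplicated(pkey)]
  if (any(multi)) tally["multiallelic"] <- sum(multi)
  x <- x[!multi, , drop = FALSE]

  if (nrow(x) == 0) {
    stop("no variants left after validation", call. = FALSE)
  }

  if ("chisq" %in% names(x)) {
    expected <- p_to_chisq(x$neg_log10_p)
    bad <- abs(x$chisq - expected) > 1e-6 * pmax(expected, 1)
    if (any(bad)) {
      tally["chisq_p_mismatch"] <- sum(bad)
      x <- x[!bad, , drop = FALSE]
      if (nrow(x) == 0) stop("no variants left after validation", call. = FALSE)
    }
  } else {
    x$chisq <- p_to_chisq(x$neg_log10_p)
  }
  x$maf <- pmin(x$eaf, 1 - x$eaf)

  attr(x, "drop_tally") <- if (length(tally)) tally else integer(0)
  x
}

#' Write a summary-statistics table
#'
#' Writes the canonical tab-delimited layout (`CHR POS ID EA OA EAF BETA SE
#' NEG_LOG10_P [N]`). P-values are written as -log10 p at full double
#' precision, so a read/write round trip is the identity on all fields
#' (including p far below double underflow).
#'
#' @param stats A validated summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  out <- tibble::tibble(
    CHR = stats$chrom, POS = stats$pos, ID = stats$id,
    EA = stats$ea, OA = stats$oa, EAF = stats$eaf,
    BETA = stats$beta, SE = stats$se, NEG_LOG10_P = stats$neg_log10_p
  )
  if ("n" %in% names(stats)) out$N <- stats$n
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an LD-score file
#'
#' Reads the LDSC `.l2.ldscore` tabular layout: columns `CHR`, `SNP`, `BP`,
#' `L2` (optionally gzipped). Rows with negative L2 and duplicated SNP ids
#' (second and later occurrences) are dropped and tallied.
#'
#' @param path Path to the LD-score table.
#' @return A tibble with columns `chrom`, `id`, `pos`, `l2`; attribute
#'   `drop_tally` counts dropped rows by reason.
#' @export
read_ldscores <- function(path) {
  raw <- .read_delim_auto(path)
  for (col in c("CHR", "SNP", "BP", "L2")) {
    if (!col %in% names(raw)) {
      stop("missing column `", col, "` in LD-score file ", path, call. = FALSE)
    }
  }
  x <- tibble::tibble(
    chrom = as.character(raw$CHR),
    id = as.character(raw$SNP),
    pos = as.integer(raw$BP),
    l2 = as.numeric(raw$L2)
  )
  tally <- c()
  bad <- !is.finite(x$l2) | x$l2 < 0
  if (any(bad)) tally["negative_l2"] <- sum(bad)
  x <- x[!bad, , drop = FALSE]
  dup <- duplicated(x$id)
  if (any(dup)) tally["duplicate_id"] <- sum(dup)
  x <- x[!dup, , drop = FALSE]
  attr(x, "drop_tally") <- if (length(tally)) tally else integer(0)
  x
}

#' Write an LD-score file
#'
#' Writes the LDSC `.l2.ldscore` layout (`CHR SNP BP L2`, tab-delimited).
#'
#' @param scores Tibble with `chrom`, `id`, `pos`, `l2`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ldscores <- function(scores, path) {
  readr::write_tsv(
    tibble::tibble(
      CHR = scores$chrom, SNP = scores$id, BP = scores$pos, L2 = scores$l2
    ),
    path,
    progress = FALSE
  )
  invisible(path)
}

#' Dropped-row tally of a validated table
#'
#' @param x A tibble returned by [read_sumstats()], [validate_sumstats()] or
#'   [read_ldscores()].
#' @return Named integer vector of dropped-row counts (empty if none).
#' @export
drop_tally <- function(x) {
  t <- attr(x, "drop_tally")
  if (is.null(t)) integer(0) else t
}
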