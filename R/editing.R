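#' Amplicon target site
#'
#' @param site_id Site identifier (e.g. `"Zm.7.1c"`).
#' @param amplicon_ref Reference amplicon sequence; amplicons are
#'   conventionally kept below 200 bp so 2x150 paired-end reads cover the
#'   target from at least one direction (a warning is raised otherwise).
#' @param window_start,window_end 0-based half-open interval on the amplicon
#'   covering PAM + protospacer (the indel-counting window).
#' @param nick_positions Optional length-2 integer vector of the Cas12a
#'   staggered-cut coordinates (upstream nick first).
#' @return An object of class `target_site`.
#' @export
target_site <- function(site_id, amplicon_ref, window_start, window_end,
                        nick_positions = NULL) {
  amplicon_ref <- normalize_dna(amplicon_ref, id = site_id)
  window_start <- as.integer(window_start); window_end <- as.integer(window_end)
  len <- nchar(amplicon_ref)
  stopifnot(window_start >= 0L, window_end > window_start, window_end <= len)
  if (len >= 200L) {
    warning(sprintf("amplicon '%s' is %d bp; amplicons are kept below 200 bp",
                    site_id, len))
  }
  structure(list(site_id = site_id, amplicon_ref = amplicon_ref,
                 window_start = window_start, window_end = window_end,
                 nick_positions = if (is.null(nick_positions)) NULL
                                  else as.integer(nick_positions)),
            class = "target_site")
}

#' Alignment parameters for amplicon indel calling
#'
#' Global-in-read, local-in-reference ("glocal") alignment with affine gaps.
#'
#' @param match,mismatch Substitution scores (defaults +2 / -3).
#' @param gap_open,gap_extend Gap penalties as negative scores (-6 / -1).
#' @param min_score Reads whose best alignment scores below this are dropped
#'   (counted, never called).
#' @return A list of alignment parameters.
#' @export
aln_params <- function(match = 2, mismatch = -3, gap_open = -6,
                       gap_extend = -1, min_score = 50) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, min_score = min_score)
}

## glocal alignment of a set of reads against the amplicon; returns, per
## read, the indel operations (deletions left-aligned) and the alignment
## score of the better orientation
align_reads_glocal <- function(reads, ref, params) {
  n <- length(reads)
  out <- vector("list", n)
  scores <- rep(-Inf, n)
  ## fast path: reads that are exact substrings of the reference carry no
  ## indel by construction
  rc <- vapply(reads, function(r) revcomp(r), "")
  exact_f <- vapply(reads, function(r) grepl(r, ref, fixed = TRUE), logical(1))
  exact_r <- !exact_f & vapply(rc, function(r) grepl(r, ref, fixed = TRUE),
                               logical(1))
  for (i in which(exact_f | exact_r)) {
    out[[i]] <- list(deletions = NULL, insertions = NULL)
    scores[i] <- params$match * nchar(reads[i])
  }
  todo <- which(!(exact_f | exact_r))
  if (length(todo)) {
    ## identical read sequences (common in amplicon data) are aligned once
    useq <- unique(reads[todo])
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
    subj <- Biostrings::DNAString(ref)
    do_aln <- function(pats) {
      Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(pats), subj, type = "global-local",
        substitutionMatrix = mat,
        gapOpening = -params$gap_open, gapExtension = -params$gap_extend)
    }
    aln_f <- do_aln(useq)
    aln_r <- do_aln(vapply(useq, revcomp, "", USE.NAMES = FALSE))
    sf <- Biostrings::score(aln_f); sr <- Biostrings::score(aln_r)
    gp_f <- as.character(Biostrings::alignedPattern(aln_f))
    gs_f <- as.character(Biostrings::alignedSubject(aln_f))
    st_f <- BiocGenerics::start(Biostrings::subject(aln_f)) - 1L
    gp_r <- as.character(Biostrings::alignedPattern(aln_r))
    gs_r <- as.character(Biostrings::alignedSubject(aln_r))
    st_r <- BiocGenerics::start(Biostrings::subject(aln_r)) - 1L
    uops <- vector("list", length(useq))
    uscore <- numeric(length(useq))
    for (k in seq_along(useq)) {
      use_r <- sr[k] > sf[k]
      uscore[k] <- if (use_r) sr[k] else sf[k]
      if (uscore[k] < params$min_score) next
      uops[[k]] <- if (use_r) {
        parse_indel_ops(gp_r[k], gs_r[k], st_r[k], ref)
      } else {
        parse_indel_ops(gp_f[k], gs_f[k], st_f[k], ref)
      }
    }
    ku <- match(reads[todo], useq)
    scores[todo] <- uscore[ku]
    out[todo] <- uops[ku]
  }
  list(ops = out, scores = scores)
}

## walk gapped pattern/subject strings, collecting deletion and insertion
## runs in 0-based reference coordinates; deletions are left-aligned
## (leftmost-indel convention) so ambiguous placements are deterministic
parse_indel_ops <- function(gp, gs, sub_start0, ref) {
  pc <- strsplit(gp, "")[[1L]]
  sc <- strsplit(gs, "")[[1L]]
  ref_chars <- strsplit(ref, "")[[1L]]
  dels <- list(); ins <- list()
  ref_pos <- sub_start0
  i <- 1L
  n <- length(pc)
  while (i <= n) {
    if (pc[i] == "-") {              # deletion from the read
      d_start <- ref_pos
      while (i <= n && pc[i] == "-") { ref_pos <- ref_pos + 1L; i <- i + 1L }
      d_end <- ref_pos
      while (d_start > 0L && ref_chars[d_start] == ref_chars[d_end]) {
        d_start <- d_start - 1L; d_end <- d_end - 1L
      }
      dels[[length(dels) + 1L]] <- c(start = d_start, end = d_end)
    } else if (sc[i] == "-") {       # insertion in the read
      len <- 0L
      while (i <= n && sc[i] == "-") { len <- len + 1L; i <- i + 1L }
      ins[[length(ins) + 1L]] <- c(pos = ref_pos, len = len)
    } else {
      ref_pos <- ref_pos + 1L
      i <- i + 1L
    }
  }
  list(deletions = if (length(dels)) do.call(rbind, dels) else NULL,
       insertions = if (length(ins)) do.call(rbind, ins) else NULL)
}

## does an op set intersect the window? Deletions intersect on overlap;
## insertions count when the insertion point lies strictly inside the window
ops_hit_window <- function(ops, ws, we) {
  if (is.null(ops)) return(FALSE)
  d <- ops$deletions
  if (!is.null(d) && any(pmax(d[, "start"], ws) < pmin(d[, "end"], we))) {
    return(TRUE)
  }
  ii <- ops$insertions
  !is.null(ii) && any(ii[, "pos"] > ws & ii[, "pos"] < we)
}

#' Call indels on amplicon reads
#'
#' Aligns each mate glocally (global in the read, local in the reference)
#' with affine gaps, trying both orientations and keeping the better one. A
#' fragment carries an indel iff either mate's alignment contains an
#' inserted or deleted base whose reference span intersects the site window
#' (amplicons are sized so reads cover the target from at least one
#' direction, and a fragment counts once). Ns align as ambiguity codes and never count as
#' indels; mates scoring below `min_score` are excluded and tallied in the
#' drop report.
#'
#' @param reads List of [read_pair()]s, or a character vector of single-end
#'   reads.
#' @param site A [target_site()].
#' @param params An [aln_params()] list.
#' @return An object of class `amplicon_callset`: `site`, `n_total_reads`,
#'   `n_indel_reads`, `indel_pct`, `per_read` (data frame), `deletions`
#'   (per-fragment deletion intervals, for profiles) and `dropped`.
#' @export
call_reads <- function(reads, site, params = aln_params()) {
  stopifnot(inherits(site, "target_site"))
  if (is.character(reads)) {
    reads <- lapply(seq_along(reads), function(i) {
      structure(list(id = sprintf("read_%d", i), read1 = reads[i],
                     read2 = NULL), class = "read_pair")
    })
  }
  ids <- vapply(reads, `[[`, "", "id")
  mate_seqs <- character(0); mate_of <- integer(0)
  for (i in seq_along(reads)) {
    mate_seqs <- c(mate_seqs, reads[[i]]$read1)
    mate_of <- c(mate_of, i)
    if (!is.null(reads[[i]]$read2)) {
      mate_seqs <- c(mate_seqs, reads[[i]]$read2)
      mate_of <- c(mate_of, i)
    }
  }
  aln <- align_reads_glocal(mate_seqs, site$amplicon_ref, params)
  aligned_ok <- aln$scores >= params$min_score
  ws <- site$window_start; we <- site$window_end

  n <- length(reads)
  frag_aligned <- frag_indel <- logical(n)
  frag_dels <- vector("list", n)
  for (k in seq_along(mate_seqs)) {
    i <- mate_of[k]
    if (!aligned_ok[k]) next
    frag_aligned[i] <- TRUE
    ops <- aln$ops[[k]]
    if (ops_hit_window(ops, ws, we)) frag_indel[i] <- TRUE
    if (!is.null(ops$deletions)) {
      frag_dels[[i]] <- rbind(frag_dels[[i]], ops$deletions)
    }
  }
  dropped <- ids[!frag_aligned]
  keep <- which(frag_aligned)
  n_total <- length(keep)
  n_indel <- sum(frag_indel[keep])
  structure(list(
    site = site,
    n_total_reads = n_total,
    n_indel_reads = n_indel,
    indel_pct = if (n_total > 0L) 100 * n_indel / n_total else NA_real_,
    per_read = data.frame(read_id = ids[keep],
                          has_indel = frag_indel[keep],
                          stringsAsFactors = FALSE),
    deletions = frag_dels[keep],
    dropped = dropped
  ), class = "amplicon_callset")
}

#' @export
print.amplicon_callset <- function(x, ...) {
  cat(sprintf("<amplicon_callset> %s: %d/%d fragments with indel (%.1f%%), %d dropped\n",
              x$site$site_id, x$n_indel_reads, x$n_total_reads,
              x$indel_pct, length(x$dropped)))
  invisible(x)
}

#' Per-position deletion profile over replicates
#'
#' For each position of a 40-bp region including the target site, computes
#' the percentage of fragments with that reference base deleted, per
#' replicate, then averages over replicates.
#'
#' @param callsets List of [call_reads()] results (replicates of one site).
#' @param site The shared [target_site()].
#' @param window_40bp Optional 0-based half-open interval; defaults to 40 bp
#'   centered on the site window.
#' @return An object of class `deletion_profile`: `positions` (0-based),
#'   `per_position_deletion_pct` (length 40, mean over replicates) and
#'   `n_replicates`.
#' @export
deletion_profile <- function(callsets, site, window_40bp = NULL) {
  stopifnot(length(callsets) >= 1L)
  if (!all(vapply(callsets, function(cs)
    identical(cs$site$site_id, site$site_id), logical(1)))) {
    stop("all callsets must share the site")
  }
  if (is.null(window_40bp)) {
    center <- (site$window_start + site$window_end) %/% 2L
    window_40bp <- c(center - 20L, center + 20L)
  }
  pos <- window_40bp[1L]:(window_40bp[2L] - 1L)
  per_rep <- vapply(callsets, function(cs) {
    if (cs$n_total_reads == 0L) stop("replicate with 0 reads")
    hit <- matrix(0, nrow = length(cs$deletions), ncol = length(pos))
    for (i in seq_along(cs$deletions)) {
      d <- cs$deletions[[i]]
      if (is.null(d)) next
      for (r in seq_len(nrow(d))) {
        hit[i, pos >= d[r, "start"] & pos < d[r, "end"]] <- 1
      }
    }
    100 * colSums(hit) / cs$n_total_reads
  }, numeric(length(pos)))
  structure(list(
    positions = pos,
    per_position_deletion_pct = rowMeans(per_rep),
    n_replicates = length(callsets)
  ), class = "deletion_profile")
}

#' Classify plants as advanceable
#'
#' A plant is advanceable when its leaf indel rate is strictly over the
#' threshold (default 10%): exactly 10.0 is not advanceable.
#'
#' @param indel_pct Numeric vector of per-plant indel percentages.
#' @param threshold Threshold in percent (default 10).
#' @return Logical vector.
#' @export
classify_advanceable <- function(indel_pct, threshold = 10.0) {
  if (any(is.na(indel_pct))) stop("missing indel_pct value")
  indel_pct > threshold
}

#' Population editing summary (per construct)
#'
#' Applies the transgene copy-number filter (by default only plants carrying
#' one or two copies are analyzed), then computes, per construct: plant
#' count, mean indel rate over the population ("average indel rate in
#' sequencing reads"), the count of advanceable plants (indel rate strictly
#' over the threshold), and the advanceable rate. Report percentages are
#' rounded half-up to 1 decimal; full precision is kept in the
#' `mean_indel_pct_full` / `advanceable_rate_pct_full` columns.
#'
#' @param plants Data frame with columns `plant_id`, `construct_id`,
#'   `copy_number` (values like `"1"`, `"2"`, `"multi"`) and `indel_pct`;
#'   an optional `site_id` column is filtered to `site_id` when given.
#' @param site_id Optional site to restrict to.
#' @param copy_filter Copy-number values retained (default `c("1", "2")`);
#'   `NULL` keeps everything.
#' @param threshold Advanceable threshold in percent (default 10).
#' @return Data frame with one row per construct.
#' @export
summarize_population <- function(plants, site_id = NULL,
                                 copy_filter = c("1", "2"), threshold = 10.0) {
  stopifnot(all(c("plant_id", "construct_id", "indel_pct") %in% names(plants)))
  if (!is.null(site_id) && "site_id" %in% names(plants)) {
    plants <- plants[plants$site_id == site_id, , drop = FALSE]
  }
  if (!is.null(copy_filter) && "copy_number" %in% names(plants)) {
    plants <- plants[as.character(plants$copy_number) %in%
                       as.character(copy_filter), , drop = FALSE]
  }
  if (!nrow(plants)) stop("no plants remain after filtering")
  out <- do.call(rbind, lapply(split(plants, plants$construct_id), function(p) {
    adv <- classify_advanceable(p$indel_pct, threshold)
    mean_full <- mean(p$indel_pct)
    rate_full <- 100 * sum(adv) / nrow(p)
    data.frame(construct_id = p$construct_id[1L],
               n_plants = nrow(p),
               mean_indel_pct = round_half_up(mean_full, 1L),
               n_advanceable = sum(adv),
               advanceable_rate_pct = round_half_up(rate_full, 1L),
               mean_indel_pct_full = mean_full,
               advanceable_rate_pct_full = rate_full,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classify promoters as active against a control and compute the hit rate
#'
#' The activity threshold at each site is the control's mean minus its
#' standard deviation (the lower bound of one standard deviation). A
#' promoter is active iff its mean editing rate is at or above that
#' threshold at every site supplied (inclusive boundary). The hit rate is
#' `100 * active / total` over the non-control promoters, rounded to the
#' nearest integer for reporting.
#'
#' @param stats Data frame with columns `promoter_id`, `site_id`, `mean`,
#'   and (for the control at least) `sd`.
#' @param control_id Promoter id of the control.
#' @return List with `active_ids`, `n_active`, `n_total`, `hit_rate_pct`
#'   (integer) and the per-site `thresholds`.
#' @export
classify_active_promoters <- function(stats, control_id) {
  stopifnot(all(c("promoter_id", "site_id", "mean") %in% names(stats)))
  ctrl <- stats[stats$promoter_id == control_id, , drop = FALSE]
  if (!nrow(ctrl)) stop("control '", control_id, "' not found")
  if (!"sd" %in% names(stats) || any(is.na(ctrl$sd))) {
    stop("control rows must carry a standard deviation")
  }
  thresholds <- setNames(ctrl$mean - ctrl$sd, ctrl$site_id)
  trt <- stats[stats$promoter_id != control_id, , drop = FALSE]
  sites <- names(thresholds)
  promoters <- unique(trt$promoter_id)
  active <- vapply(promoters, function(p) {
    rows <- trt[trt$promoter_id == p, , drop = FALSE]
    all(vapply(sites, function(s) {
      r <- rows[rows$site_id == s, , drop = FALSE]
      nrow(r) > 0L && all(r$mean >= thresholds[[s]])
    }, logical(1)))
  }, logical(1))
  n_total <- length(promoters)
  n_active <- sum(active)
  list(active_ids = promoters[active], n_active = n_active, n_total = n_total,
       hit_rate_pct = as.integer(round_half_up(100 * n_active / n_total, 0L)),
       thresholds = thresholds)
}

#' Luciferase transformation quality control
#'
#' A treatment passes when its luminescence is at least `min_ratio`-fold
#' (inclusive) over the no-DNA control.
#'
#' @param treatment_lum Numeric vector of treatment luminescence values.
#' @param no_dna_lum Positive scalar, the no-DNA control luminescence.
#' @param min_ratio Minimum fold-change (default 100).
#' @return Logical vector of pass/fail.
#' @export
luciferase_qc <- function(treatment_lum, no_dna_lum, min_ratio = 100) {
  if (!is.numeric(no_dna_lum) || length(no_dna_lum) != 1L || no_dna_lum <= 0) {
    stop("no-DNA control luminescence must be a positive scalar")
  }
  treatment_lum / no_dna_lum >= min_ratio
}

#' Housekeeping-normalized expression
#'
#' Divides the target expression value by the geometric mean of the
#' housekeeping genes' values (e.g. eIF1A and EF1a); invariant to a common
#' scale factor applied to all inputs.
#'
#' @param target_value Positive scalar.
#' @param housekeeping_values Positive numeric vector, length >= 1.
#' @return Normalized expression (scalar).
#' @export
normalize_expression <- function(target_value, housekeeping_values) {
  if (length(housekeeping_values) < 1L) stop("need >= 1 housekeeping value")
  if (any(c(target_value, housekeeping_values) <= 0)) {
    stop("expression values must be positive")
  }
  target_value / exp(mean(log(housekeeping_values)))
}

#' Compare editing rates or expression across groups
#'
#' Thin adapter over standard nonparametric routines: an omnibus
#' Kruskal-Wallis rank sum test followed by pairwise Wilcoxon rank sum
#' tests (exact where ties permit).
#'
#' @param values Numeric vector of per-unit values.
#' @param groups Factor/character vector of group labels, same length.
#' @return List with `omnibus` (statistic, p) and `pairwise` (data frame:
#'   group1, group2, statistic, p, direction of the median difference).
#' @export
compare_rates <- function(values, groups) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 observations; offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  kw <- kruskal.test(values, groups)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    x <- values[groups == g1]; y <- values[groups == g2]
    wt <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    data.frame(group1 = g1, group2 = g2,
               statistic = unname(wt$statistic), p = wt$p.value,
               direction = sign(stats::median(x) - stats::median(y)),
               stringsAsFactors = FALSE)
  }))
  list(omnibus = list(statistic = unname(kw$statistic), p = kw$p.value),
       pairwise = pw)
}

#' Spearman correlation between paired construct-level means
#'
#' @param x,y Paired numeric vectors (e.g. protoplast vs in-planta mean
#'   rates per construct).
#' @return List with `rho` and `p`.
#' @export
correlate_rates <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
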