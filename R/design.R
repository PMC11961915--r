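#' Simulated-annealing schedule
#'
#' Geometric cooling: the temperature is multiplied by a constant factor each
#' step so that `t_final` is reached exactly at `n_steps`.
#'
#' @param t_initial,t_final Start and end temperatures (score units). The
#'   default start temperature (2.0) follows the initial-acceptance-ratio
#'   heuristic: a single-base substitution can swap up to `word_length` table
#'   terms at once, giving adverse score deltas on the order of one score
#'   unit on short designs, which should still be accepted often early on.
#' @param n_steps Number of cooling steps (default 20000).
#' @param moves_per_step Proposals evaluated at each temperature (default 1).
#' @param seed Integer seed; the whole design run is reproducible from it.
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t_initial = 2.0, t_final = 1e-3,
                            n_steps = 20000L, moves_per_step = 1L, seed = 1L) {
  stopifnot(t_initial > t_final, t_final > 0, n_steps >= 1L,
            moves_per_step >= 1L)
  structure(list(t_initial = t_initial, t_final = t_final,
                 n_steps = as.integer(n_steps),
                 moves_per_step = as.integer(moves_per_step),
                 seed = as.integer(seed)),
            class = "anneal_schedule")
}

#' Default motif seeding for promoter design
#'
#' One motif per promoter element class, with TSS-relative start intervals
#' consistent with the training-set layout: an MSP (RGCCCR) anywhere in
#' `[-160, -90]`, a USE (TCCCACATCG) in `[-63, -61]`, and a TATA (TATAWA)
#' in `[-31, -29]`, which keeps the USE-to-TATA and TATA-to-TSS gaps inside
#' the spacing learned from the training grammar.
#'
#' @return List of seed motif specs (`name`, `consensus`, `interval`).
#' @export
default_seed_motifs <- function() {
  list(
    list(name = "MSP", consensus = "RGCCCR", interval = c(-160L, -90L)),
    list(name = "USE", consensus = "TCCCACATCG", interval = c(-63L, -61L)),
    list(name = "TATA", consensus = "TATAWA", interval = c(-31L, -29L))
  )
}

#' Design-run configuration
#'
#' @param length Designed promoter length in bp (default 500; the design's
#'   3' end sits at the TSS).
#' @param seed_motifs List of seed motif specs as in [default_seed_motifs()];
#'   each may carry a `motif_model` in place of a consensus string.
#' @param motif_lock If `TRUE` (default) seeded motif positions are locked
#'   against mutation so they survive annealing verbatim.
#' @param screen_rules Composition screens applied by [screen_design()].
#' @param schedule An [anneal_schedule()].
#' @return An object of class `design_config`.
#' @export
design_config <- function(length = 500L, seed_motifs = default_seed_motifs(),
                          motif_lock = TRUE, screen_rules = default_screen_rules(),
                          schedule = anneal_schedule()) {
  structure(list(length = as.integer(length), seed_motifs = seed_motifs,
                 motif_lock = isTRUE(motif_lock), screen_rules = screen_rules,
                 schedule = schedule),
            class = "design_config")
}

## place seed motifs: sample a start in each TSS-relative interval (uniform),
## resolve degenerate letters uniformly, reject overlaps
place_seed_motifs <- function(seed_motifs, length, max_tries = 200L) {
  if (!length(seed_motifs)) {
    return(data.frame(name = character(), consensus = character(),
                      start = integer(), end = integer(),
                      realized = character(), stringsAsFactors = FALSE))
  }
  placements <- NULL
  for (attempt in seq_len(max_tries)) {
    rows <- lapply(seed_motifs, function(sm) {
      consensus <- if (inherits(sm$motif, "motif_model")) sm$motif$consensus
                   else if (!is.null(sm$consensus)) sm$consensus
                   else sm$motif
      wlm <- nchar(consensus)
      iv <- as.integer(sm$interval)
      start <- length + sample(iv[1L]:iv[2L], 1L)   # TSS-relative -> 0-based index
      if (start < 0L || start + wlm > length) {
        stop(sprintf("seed motif %s (%s) does not fit in a %d-bp design",
                     sm$name, consensus, length))
      }
      sets <- IUPAC_SETS[strsplit(toupper(consensus), "")[[1L]]]
      realized <- paste(vapply(sets, function(s) s[sample.int(length(s), 1L)], ""),
                        collapse = "")
      data.frame(name = sm$name %||% consensus, consensus = consensus,
                 start = start, end = start + wlm, realized = realized,
                 stringsAsFactors = FALSE)
    })
    placements <- do.call(rbind, rows)
    ord <- order(placements$start)
    ends <- placements$end[ord]; starts <- placements$start[ord]
    if (all(head(ends, -1L) <= starts[-1L])) return(placements)
  }
  stop("seed motif placement infeasible: intervals overlap in every draw")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Design a novel promoter by seeded simulated annealing
#'
#' Draws a uniform random sequence, places the seed motifs at positions drawn
#' from their TSS-relative intervals (degenerate letters resolved uniformly),
#' then runs a Metropolis loop proposing single-base substitutions at random
#' unlocked positions, accepting improvements always and deteriorations with
#' probability `exp(delta/T)` under geometric cooling. Returns the
#' best-scoring sequence visited. Fully reproducible given the schedule seed.
#'
#' @param model A [train_model()] scoring model.
#' @param config A [design_config()]; `config$length` must not exceed the
#'   model window's upstream arm (designs are promoter-only, 3'-anchored at
#'   the TSS).
#' @return An object of class `designed_promoter` with fields `sequence`,
#'   `score_trace`, `final_breakdown`, `seeded_placements`,
#'   `config_fingerprint` and `seed`.
#' @export
design_promoter <- function(model, config = design_config()) {
  stopifnot(inherits(model, "promoter_score_model"),
            inherits(config, "design_config"))
  L <- config$length
  wl <- model$word_length
  if (L < wl) stop("design length shorter than model word_length")
  offset <- model_offset(L, model)   # validates against the model window

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$schedule$seed)

  base0 <- sample.int(4L, L, replace = TRUE) - 1L
  placements <- place_seed_motifs(config$seed_motifs, L)
  locked <- rep(FALSE, L)
  for (i in seq_len(nrow(placements))) {
    idx <- (placements$start[i] + 1L):placements$end[i]
    base0[idx] <- dna_to_int(placements$realized[i])
    if (config$motif_lock) locked[idx] <- TRUE
  }

  win_len <- window_length(model$window)
  binmap <- kmer_bin_map(win_len, wl, model$n_bins)[offset + seq_len(L - wl + 1L)]
  res <- anneal_design_cpp(
    base0, locked, log(model$freq_table), model$enr_table, binmap, wl,
    as.numeric(model$weights),
    config$schedule$n_steps, config$schedule$t_initial,
    config$schedule$t_final, config$schedule$moves_per_step,
    trace_every = max(1L, config$schedule$n_steps %/% 2000L))

  sequence <- int_to_dna(res$best_seq)
  breakdown <- score_sequence(sequence, model)
  trace <- as.data.frame(res$trace)
  names(trace) <- c("step", "current_total", "best_total")
  structure(list(
    sequence = sequence,
    score_trace = trace,
    final_breakdown = breakdown,
    best_total = breakdown$total,
    seeded_placements = placements,
    config_fingerprint = fingerprint_string(paste(
      L, config$motif_lock, config$schedule$n_steps,
      config$schedule$t_initial, config$schedule$t_final,
      paste(vapply(config$seed_motifs, function(m)
        paste0(m$name %||% "", ":", m$consensus %||% ""), ""), collapse = ";"),
      sep = "|")),
    seed = config$schedule$seed
  ), class = "designed_promoter")
}

#' @export
print.designed_promoter <- function(x, ...) {
  cat(sprintf("<designed_promoter> %d bp, total score %.4f (seed %d)\n",
              nchar(x$sequence), x$best_total, x$seed))
  invisible(x)
}

#' Trim a designed promoter from the 5' end
#'
#' Trims only from the 5' (TSS-distal) end so the TSS-proximal core is
#' preserved. Among candidate lengths in `target_range` whose trimmed
#' sequence still annotates as a valid promoter (TATA, USE and at least one
#' MSP, spacing satisfied), the highest partial-window score is chosen, ties
#' going to the longest. If no in-range length retains the elements, the
#' shortest longer length that does is returned with a `trim_warning`
#' attribute.
#'
#' @param designed A [design_promoter()] result (or any object with a
#'   `sequence` field whose 3' end is the TSS).
#' @param target_range Length-2 integer vector, allowed trimmed lengths
#'   (default `c(280, 300)`).
#' @param defs Element definitions ([default_element_defs()]).
#' @param spacing Spacing rule ([default_spacing_rule()] or learned).
#' @param model Optional scoring model used to rank candidate lengths; if
#'   `NULL` the longest valid length is returned.
#' @return The trimmed DNA string (attribute `trim_warning` set if the
#'   returned length falls outside `target_range`).
#' @export
trim_promoter <- function(designed, target_range = c(280L, 300L),
                          defs = default_element_defs(),
                          spacing = default_spacing_rule(), model = NULL) {
  seq <- if (is.character(designed)) designed else designed$sequence
  L <- nchar(seq)
  target_range <- as.integer(target_range)
  if (L <= max(target_range)) {
    stop(sprintf("design length %d is not longer than target range max %d",
                 L, max(target_range)))
  }
  valid_at <- function(len) {
    rec <- promoter_record("trim", substr(seq, L - len + 1L, L), len)
    ann <- annotate_elements(rec, defs = defs, spacing = spacing)
    ann$valid
  }
  cand <- target_range[1L]:target_range[2L]
  ok <- vapply(cand, valid_at, logical(1))
  if (any(ok)) {
    keep <- cand[ok]
    if (is.null(model)) {
      best_len <- max(keep)
    } else {
      scores <- vapply(keep, function(len)
        score_sequence(substr(seq, L - len + 1L, L), model)$total, 0)
      best_len <- max(keep[scores >= max(scores) - 1e-12])
    }
    return(substr(seq, L - best_len + 1L, L))
  }
  for (len in (max(target_range) + 1L):L) {
    if (valid_at(len)) {
      warning(sprintf(
        "no length in [%d, %d] retains all elements; returning %d bp",
        target_range[1L], target_range[2L], len))
      out <- substr(seq, L - len + 1L, L)
      attr(out, "trim_warning") <- TRUE
      return(out)
    }
  }
  full <- annotate_elements(promoter_record("trim", seq, L),
                            defs = defs, spacing = spacing)
  stop("elements cannot be retained at any allowed length; missing: ",
       paste(full$missing, collapse = ", "))
}

#' Default composition screen rules
#'
#' @param homopolymer_min Minimum homopolymer run length to flag (default 6).
#' @param t_run_min Minimum T-run length for the Pol III terminator-resemblance
#'   warning (default 4).
#' @param gc_range Acceptable GC fraction interval (default `[0.25, 0.75]`).
#' @param forbidden_sites Character vector of exact sites to flag (e.g.
#'   cloning sites).
#' @return A list of screen rules.
#' @export
default_screen_rules <- function(homopolymer_min = 6L, t_run_min = 4L,
                                 gc_range = c(0.25, 0.75),
                                 forbidden_sites = character()) {
  list(homopolymer_min = as.integer(homopolymer_min),
       t_run_min = as.integer(t_run_min),
       gc_range = gc_range, forbidden_sites = forbidden_sites)
}

#' Screen a designed sequence for composition risks
#'
#' Generic sequence-composition screens applied before use: long homopolymer
#' runs, T-runs that resemble Pol III terminators, out-of-range GC fraction,
#' and user-listed forbidden sites. Flags only; nothing errors.
#'
#' @param seq DNA string.
#' @param rules A [default_screen_rules()] list.
#' @return Data frame with columns `rule`, `position` (0-based, `NA` for
#'   global rules) and `detail`; zero rows if nothing fires.
#' @export
screen_design <- function(seq, rules = default_screen_rules()) {
  flags <- list()
  chars <- strsplit(seq, "")[[1L]]
  runs <- rle(chars)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths   # 0-based
  for (i in seq_along(runs$lengths)) {
    if (runs$lengths[i] >= rules$homopolymer_min) {
      flags[[length(flags) + 1L]] <- data.frame(
        rule = "homopolymer", position = starts[i],
        detail = sprintf("%s x %d", runs$values[i], runs$lengths[i]))
    }
    if (runs$values[i] == "T" && runs$lengths[i] >= rules$t_run_min) {
      flags[[length(flags) + 1L]] <- data.frame(
        rule = "t_run_terminator", position = starts[i],
        detail = sprintf("T x %d resembles a Pol III terminator", runs$lengths[i]))
    }
  }
  gc <- mean(chars %in% c("G", "C"))
  if (gc < rules$gc_range[1L] || gc > rules$gc_range[2L]) {
    flags[[length(flags) + 1L]] <- data.frame(
      rule = "gc_fraction", position = NA_integer_,
      detail = sprintf("GC fraction %.3f outside [%.2f, %.2f]",
                       gc, rules$gc_range[1L], rules$gc_range[2L]))
  }
  for (site in rules$forbidden_sites) {
    hits <- match_consensus(seq, site)
    for (h in hits) {
      flags[[length(flags) + 1L]] <- data.frame(
        rule = "forbidden_site", position = h, detail = site)
    }
  }
  if (!length(flags)) {
    return(data.frame(rule = character(), position = integer(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}
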