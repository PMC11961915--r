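#' Specification of a synthetic promoter training set
#'
#' The generator emulates the structure of the monocot U6/U3 training set:
#' each promoter is a TSS-anchored window with a TATA box near -30, a USE
#' whose end-to-TATA gap is nearly constant, and an MSP somewhere in a broad
#' 5' interval, planted over a first-order (dinucleotide) Markov background.
#'
#' @param n_u6,n_u3 Number of U6 / U3 records (defaults 42 and 24).
#' @param window A [window_spec()] (default 500 upstream / 50 downstream).
#' @param msp_offset_range TSS-relative start interval for the MSP
#'   (default `[-160, -90]`).
#' @param use_tata_gap,use_tata_jitter USE end-to-TATA start gap, mean and
#'   +/- jitter (defaults 22 and 1).
#' @param tata_offset,tata_jitter TATA start offset and jitter (-30 +/- 1).
#' @param dinuc_trans Optional 4x4 base transition matrix (rows = from base
#'   A,C,G,T); default is a mildly AT-rich composition with CpG depletion.
#' @param seed Integer seed; generation is bit-reproducible from it.
#' @return An object of class `training_set_spec`.
#' @export
training_set_spec <- function(n_u6 = 42L, n_u3 = 24L, window = window_spec(),
                              msp_offset_range = c(-160L, -90L),
                              use_tata_gap = 22L, use_tata_jitter = 1L,
                              tata_offset = -30L, tata_jitter = 1L,
                              dinuc_trans = NULL, seed = 1L) {
  if (is.null(dinuc_trans)) {
    p <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
    dinuc_trans <- matrix(rep(p, 4L), nrow = 4L, byrow = TRUE,
                          dimnames = list(DNA_BASES, DNA_BASES))
    dinuc_trans["G", "C"] <- dinuc_trans["G", "C"] * 0.6   # CpG depletion
    dinuc_trans["T", "A"] <- dinuc_trans["T", "A"] * 0.85  # TpA depletion
    dinuc_trans <- dinuc_trans / rowSums(dinuc_trans)
  }
  stopifnot(n_u6 >= 0L, n_u3 >= 0L, n_u6 + n_u3 >= 1L,
            all(dim(dinuc_trans) == c(4L, 4L)),
            msp_offset_range[1L] <= msp_offset_range[2L])
  ## layout feasibility: MSP must end 5' of the USE start
  use_start_min <- tata_offset - tata_jitter -
    (use_tata_gap + use_tata_jitter) - 10L
  if (msp_offset_range[2L] + 6L > use_start_min) {
    stop("infeasible layout: MSP interval can collide with the USE")
  }
  if (-(msp_offset_range[1L]) > window$upstream) {
    stop("infeasible layout: MSP interval outside the upstream window")
  }
  structure(list(n_u6 = as.integer(n_u6), n_u3 = as.integer(n_u3),
                 window = window, msp_offset_range = as.integer(msp_offset_range),
                 use_tata_gap = as.integer(use_tata_gap),
                 use_tata_jitter = as.integer(use_tata_jitter),
                 tata_offset = as.integer(tata_offset),
                 tata_jitter = as.integer(tata_jitter),
                 dinuc_trans = dinuc_trans, seed = as.integer(seed)),
            class = "training_set_spec")
}

## first-order Markov background sequence
markov_background <- function(n, trans) {
  statio <- rep(0.25, 4L)
  out <- integer(n)
  out[1L] <- sample.int(4L, 1L, prob = statio)
  for (i in 2:n) out[i] <- sample.int(4L, 1L, prob = trans[out[i - 1L], ])
  int_to_dna(out - 1L)
}

resolve_iupac_random <- function(consensus) {
  sets <- IUPAC_SETS[strsplit(consensus, "")[[1L]]]
  paste(vapply(sets, function(s) s[sample.int(length(s), 1L)], ""), collapse = "")
}

#' Generate a synthetic promoter training set with known element truth
#'
#' @param spec A [training_set_spec()].
#' @return List with `records` (list of [promoter_record()]s) and `truth`
#'   (data frame of planted element intervals, TSS-relative half-open).
#' @export
generate_training_set <- function(spec = training_set_spec()) {
  stopifnot(inherits(spec, "training_set_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  up <- spec$window$upstream
  L <- window_length(spec$window)
  n <- spec$n_u6 + spec$n_u3
  classes <- c(rep("U6", spec$n_u6), rep("U3", spec$n_u3))
  species_pool <- c("Zea mays", "Sorghum bicolor", "Oryza sativa",
                    "Triticum aestivum", "Hordeum vulgare",
                    "Setaria italica", "Saccharum officinarum")
  records <- vector("list", n)
  truth <- list()
  for (i in seq_len(n)) {
    seq_chars <- strsplit(markov_background(L, spec$dinuc_trans), "")[[1L]]
    jit <- function(j) if (j > 0L) sample((-j):j, 1L) else 0L
    tata_start <- spec$tata_offset + jit(spec$tata_jitter)
    gap <- spec$use_tata_gap + jit(spec$use_tata_jitter)
    use_end <- tata_start - gap
    use_start <- use_end - 10L
    msp_start <- sample(spec$msp_offset_range[1L]:spec$msp_offset_range[2L], 1L)
    plant <- list(
      MSP = list(start = msp_start, seq = resolve_iupac_random("RGCCCR")),
      USE = list(start = use_start, seq = "TCCCACATCG"),
      TATA = list(start = tata_start, seq = resolve_iupac_random("TATAWA"))
    )
    id <- sprintf("%s_%03d", ifelse(classes[i] == "U6", "synU6", "synU3"), i)
    for (el in names(plant)) {
      st <- plant[[el]]$start; sq <- plant[[el]]$seq
      idx <- (up + st + 1L):(up + st + nchar(sq))
      seq_chars[idx] <- strsplit(sq, "")[[1L]]
      truth[[length(truth) + 1L]] <- data.frame(
        id = id, snrna_class = classes[i], element = el,
        start = st, end = st + nchar(sq), planted_seq = sq,
        stringsAsFactors = FALSE)
    }
    records[[i]] <- promoter_record(
      id, paste(seq_chars, collapse = ""), tss_index = up,
      species = sample(species_pool, 1L), snrna_class = classes[i])
  }
  list(records = records, truth = do.call(rbind, truth))
}

#' Specification of a simulated edited-amplicon read set
#'
#' Deletions are drawn uniform in `del_len_range` and centered on the
#' upstream nick of the Cas12a staggered cut, emulating the observed
#' concentration of 8-10 bp deletions there. The edited-fragment count is
#' deterministic (`round(true_edit_rate * n_fragments)`) by default so
#' generator-versus-caller comparisons are exact; `binomial = TRUE` restores
#' sampling.
#'
#' @param site A [target_site()] (see [synthetic_target_site()]).
#' @param true_edit_rate Fraction of edited fragments, in `[0, 1]`.
#' @param n_fragments Number of read pairs to generate.
#' @param del_len_range Deletion length interval (default `c(8, 10)`).
#' @param insertion_prob Probability an edited fragment carries a 1-3 bp
#'   insertion instead of a deletion (default 0).
#' @param error_rate Uniform per-base substitution error rate (default 0).
#' @param read_length Read length (default 150, emulating 2x150 bp).
#' @param binomial Draw the edited count from a Binomial instead of rounding
#'   the expectation.
#' @param seed Integer seed.
#' @return An object of class `edit_sim_spec`.
#' @export
edit_sim_spec <- function(site, true_edit_rate, n_fragments,
                          del_len_range = c(8L, 10L), insertion_prob = 0,
                          error_rate = 0, read_length = 150L,
                          binomial = FALSE, seed = 1L) {
  stopifnot(inherits(site, "target_site"),
            true_edit_rate >= 0, true_edit_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            insertion_prob >= 0, insertion_prob <= 1, n_fragments >= 1L)
  if (is.null(site$nick_positions)) stop("site needs nick_positions")
  nick <- site$nick_positions[1L]
  ref_len <- nchar(site$amplicon_ref)
  if (nick - max(del_len_range) < 0L || nick + max(del_len_range) > ref_len) {
    stop("deletion longer than the available window context around the nick")
  }
  structure(list(site = site, true_edit_rate = true_edit_rate,
                 n_fragments = as.integer(n_fragments),
                 del_len_range = as.integer(del_len_range),
                 insertion_prob = insertion_prob, error_rate = error_rate,
                 read_length = as.integer(read_length),
                 binomial = isTRUE(binomial), seed = as.integer(seed)),
            class = "edit_sim_spec")
}

#' Construct a synthetic amplicon target site
#'
#' Random amplicon with a PAM + 23-bp protospacer window near the middle and
#' Cas12a-style staggered nick positions (18 and 23 nt from the PAM-proximal
#' end of the protospacer). Labelled synthetic; no genomic provenance.
#'
#' @param seed Integer seed.
#' @param amplicon_length Amplicon length (default 180, below the 200-bp
#'   convention).
#' @param site_id Identifier (default `"synthetic_site"`).
#' @return A [target_site()].
#' @export
synthetic_target_site <- function(seed = 1L, amplicon_length = 180L,
                                  site_id = "synthetic_site") {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ref <- int_to_dna(sample.int(4L, amplicon_length, replace = TRUE) - 1L)
  ws <- (amplicon_length - 27L) %/% 2L      # 4-bp PAM + 23-bp protospacer
  we <- ws + 27L
  target_site(site_id, ref, ws, we,
              nick_positions = c(ws + 4L + 18L, ws + 4L + 23L))
}

#' Generate edited paired-end reads with a per-fragment truth table
#'
#' @param spec An [edit_sim_spec()].
#' @return List with `pairs` (list of [read_pair()]s), `truth` (data frame:
#'   fragment id, edited flag, deletion/insertion coordinates) and the
#'   `site`.
#' @export
generate_edited_reads <- function(spec) {
  stopifnot(inherits(spec, "edit_sim_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  ref <- spec$site$amplicon_ref
  ref_len <- nchar(ref)
  nick <- spec$site$nick_positions[1L]
  n <- spec$n_fragments
  n_edit <- if (spec$binomial) stats::rbinom(1L, n, spec$true_edit_rate)
            else as.integer(round(spec$true_edit_rate * n))
  edited <- logical(n)
  edited[sample.int(n, n_edit)] <- TRUE

  pairs <- vector("list", n)
  truth <- data.frame(fragment_id = sprintf("frag_%04d", seq_len(n)),
                      edited = edited, del_start = NA_integer_,
                      del_end = NA_integer_, ins_pos = NA_integer_,
                      ins_len = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    frag <- ref
    if (edited[i]) {
      if (spec$insertion_prob > 0 && runif(1L) < spec$insertion_prob) {
        len <- sample(1:3, 1L)
        ins <- int_to_dna(sample.int(4L, len, replace = TRUE) - 1L)
        frag <- paste0(substr(ref, 1L, nick), ins,
                       substr(ref, nick + 1L, ref_len))
        truth$ins_pos[i] <- nick; truth$ins_len[i] <- len
      } else {
        len <- if (spec$del_len_range[1L] == spec$del_len_range[2L])
          spec$del_len_range[1L]
        else sample(spec$del_len_range[1L]:spec$del_len_range[2L], 1L)
        d_start <- nick - len %/% 2L
        d_end <- d_start + len
        frag <- paste0(substr(ref, 1L, d_start), substr(ref, d_end + 1L, ref_len))
        truth$del_start[i] <- d_start; truth$del_end[i] <- d_end
      }
    }
    if (spec$error_rate > 0) {
      chars <- strsplit(frag, "")[[1L]]
      hit <- which(runif(length(chars)) < spec$error_rate)
      for (h in hit) {
        chars[h] <- sample(setdiff(DNA_BASES, chars[h]), 1L)
      }
      frag <- paste(chars, collapse = "")
    }
    flen <- nchar(frag)
    r1 <- substr(frag, 1L, min(spec$read_length, flen))
    r2 <- revcomp(substr(frag, max(1L, flen - spec$read_length + 1L), flen))
    pairs[[i]] <- read_pair(truth$fragment_id[i], r1, r2)
  }
  list(pairs = pairs, truth = truth, site = spec$site)
}

#' Generate a per-plant editing population with known advanceable fraction
#'
#' Per construct, plant indel rates are drawn from a Beta distribution
#' scaled to `[0, 100]`; the truth table carries the exact advanceable
#' fraction `P(Beta > threshold/100)`.
#'
#' @param constructs Data frame with columns `construct_id`, `n_plants`,
#'   `shape1`, `shape2` (Beta parameters).
#' @param copy_probs Sampling probabilities for copy numbers
#'   `c("1", "2", "multi")` (default `c(0.45, 0.35, 0.20)`).
#' @param threshold Advanceable threshold in percent (default 10).
#' @param site_id Site label attached to every row.
#' @param seed Integer seed.
#' @return List with `plants` (per-plant data frame) and `truth`
#'   (per-construct exact advanceable fraction).
#' @export
generate_population <- function(constructs, copy_probs = c(0.45, 0.35, 0.20),
                                threshold = 10.0, site_id = "synthetic_site",
                                seed = 1L) {
  stopifnot(all(c("construct_id", "n_plants", "shape1", "shape2") %in%
                  names(constructs)))
  if (any(constructs$shape1 <= 0 | constructs$shape2 <= 0)) {
    stop("Beta shape parameters must be positive")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  plants <- do.call(rbind, lapply(seq_len(nrow(constructs)), function(i) {
    cc <- constructs[i, ]
    data.frame(
      plant_id = sprintf("%s_plant_%04d", cc$construct_id, seq_len(cc$n_plants)),
      construct_id = cc$construct_id,
      copy_number = sample(c("1", "2", "multi"), cc$n_plants,
                           replace = TRUE, prob = copy_probs),
      site_id = site_id,
      indel_pct = 100 * rbeta(cc$n_plants, cc$shape1, cc$shape2),
      stringsAsFactors = FALSE)
  }))
  truth <- data.frame(
    construct_id = constructs$construct_id,
    true_advanceable_fraction = pbeta(threshold / 100, constructs$shape1,
                                      constructs$shape2, lower.tail = FALSE),
    stringsAsFactors = FALSE)
  list(plants = plants, truth = truth)
}
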