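#' Construct a lottery option
#'
#' An option in the cued-lottery task is a reward magnitude paired with a
#' delivery probability: risky options pay off with probability 0.5, safe
#' options with certainty.
#'
#' @param magnitude Reward volume in microliters (>= 0).
#' @param probability Reward probability; must be 0.5 (risky) or 1 (safe).
#' @return An object of class `lottery_option` with fields `magnitude`,
#'   `probability` and `kind` ("risky" or "safe").
#' @examples
#' expected_value(lottery_option(240, 0.5))  # 120
#' @export
lottery_option <- function(magnitude, probability) {
  if (!is.numeric(magnitude) || length(magnitude) != 1L || is.na(magnitude) ||
      magnitude < 0) {
    stop("`magnitude` must be a single non-negative number (microliters)")
  }
  if (!probability %in% c(0.5, 1)) {
    stop("`probability` must be 0.5 (risky) or 1 (safe)")
  }
  structure(
    list(magnitude = magnitude, probability = probability,
         kind = if (probability == 0.5) "risky" else "safe"),
    class = "lottery_option"
  )
}

#' Expected value of a lottery option
#'
#' @param option A `lottery_option`, or a numeric magnitude (microliters)
#'   combined with `probability`.
#' @param probability Reward probability, used when `option` is numeric.
#' @return Expected value in microliters: magnitude x probability.
#' @examples
#' expected_value(60, 1)    # 60
#' expected_value(5, 0.5)   # 2.5: the blank-chart 5 ul risky cue
#' @export
expected_value <- function(option, probability = NULL) {
  if (inherits(option, "lottery_option")) {
    return(option$magnitude * option$probability)
  }
  if (is.numeric(option)) {
    if (any(option < 0)) stop("reward magnitude must be non-negative")
    if (is.null(probability)) stop("`probability` required for numeric input")
    return(option * probability)
  }
  stop("`option` must be a lottery_option or numeric magnitude")
}

# Safe-option magnitudes for payoff blocks 1-4 (microliters).
.safe_magnitudes <- c(60, 120, 180, 240)

# Risky magnitudes per block: centered on 2 x safe so that the middle pair
# (LP3) matches the safe option's expected value exactly, on the task's 60 ul
# grid. The 0 entry in block 1 is the blank pie chart, which pays 5 ul.
.risky_magnitudes <- function(safe_magnitude) {
  m <- 2 * safe_magnitude + c(-120, -60, 0, 60, 120)
  m[m == 0] <- 5
  m
}

#' Build the four payoff blocks
#'
#' Each block pairs one fixed safe option with five risky options whose
#' magnitudes increase in 60 ul steps; the middle lottery pair (LP3) always has
#' equal risky and safe expected values. The block's value range runs from 0
#' (the risky no-reward outcome) to the largest risky magnitude.
#'
#' @return A list of 4 objects of class `payoff_block`, each with fields
#'   `block_id`, `safe_magnitude`, `risky_magnitudes`, `v_min`, `v_max` and a
#'   `pairs` data frame (lp_index, safe_mag_ul, risky_mag_ul, ev_safe, ev_risky).
#' @examples
#' blocks <- build_payoff_blocks()
#' value_range(blocks[[2]])  # c(0, 360)
#' @export
build_payoff_blocks <- function() {
  lapply(1:4, function(b) {
    safe <- .safe_magnitudes[b]
    risky <- .risky_magnitudes(safe)
    pairs <- data.frame(
      block_id = b,
      lp_index = 1:5,
      safe_mag_ul = safe,
      risky_mag_ul = risky,
      ev_safe = safe,
      ev_risky = risky * 0.5
    )
    structure(
      list(block_id = b, safe_magnitude = safe, risky_magnitudes = risky,
           v_min = 0, v_max = max(2 * safe + 120), pairs = pairs),
      class = "payoff_block"
    )
  })
}

#' All 20 lottery pairs as one table
#'
#' @return A 20-row data frame (4 blocks x 5 pairs) with columns `block_id`,
#'   `lp_index`, `safe_mag_ul`, `risky_mag_ul`, `ev_safe`, `ev_risky`,
#'   `v_min`, `v_max`.
#' @export
lottery_pairs <- function() {
  blocks <- build_payoff_blocks()
  out <- do.call(rbind, lapply(blocks, function(b) {
    cbind(b$pairs, v_min = b$v_min, v_max = b$v_max)
  }))
  rownames(out) <- NULL
  out
}

#' Value range of a payoff block
#'
#' @param block A `payoff_block`.
#' @return `c(v_min, v_max)` in microliters; v_min is 0 because the risky
#'   option can pay nothing, v_max is the largest risky magnitude.
#' @export
value_range <- function(block) {
  stopifnot(inherits(block, "payoff_block"))
  c(block$v_min, block$v_max)
}

#' Build a full session trial schedule
#'
#' A session presents the four payoff blocks in random order, 86 trials each:
#' 36 forced-choice trials (6 repeats of 6 instruction conditions -- the five
#' risky-instructed pairs plus one safe-instructed condition -- in random
#' order) followed by 50 free-choice trials (10 repeats of the 5 pairs in
#' random order). The side of the risky target is drawn once per block and
#' fixed. Safe-instructed trials display a lottery pair drawn uniformly.
#'
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return A 344-row data frame of class `trial_schedule` with columns
#'   `block_id`, `trial` (1-86 within block), `context` ("forced"/"free"),
#'   `lp_index`, `safe_mag_ul`, `risky_mag_ul`, `ev_safe`, `ev_risky`,
#'   `instructed` ("risky"/"safe"/"none"), `risky_side` ("left"/"right"),
#'   `v_min`, `v_max`.
#' @export
build_trial_schedule <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  pairs <- lottery_pairs()
  with_seed(seed, {
    block_order <- sample(1:4)
    rows <- lapply(block_order, function(b) {
      bp <- pairs[pairs$block_id == b, ]
      risky_side <- sample(c("left", "right"), 1L)
      # forced phase: 6 repeats x (5 risky-instructed + 1 safe-instructed)
      cond_lp <- rep(c(1:5, NA_integer_), times = 6)
      cond_instr <- rep(c(rep("risky", 5), "safe"), times = 6)
      ord <- sample(length(cond_lp))
      cond_lp <- cond_lp[ord]
      cond_instr <- cond_instr[ord]
      cond_lp[is.na(cond_lp)] <- sample(1:5, sum(is.na(cond_lp)), replace = TRUE)
      # free phase: 10 repeats x 5 pairs
      free_lp <- sample(rep(1:5, times = 10))
      lp <- c(cond_lp, free_lp)
      data.frame(
        block_id = b,
        trial = seq_len(86L),
        context = rep(c("forced", "free"), c(36L, 50L)),
        lp_index = lp,
        safe_mag_ul = bp$safe_mag_ul[lp],
        risky_mag_ul = bp$risky_mag_ul[lp],
        ev_safe = bp$ev_safe[lp],
        ev_risky = bp$ev_risky[lp],
        instructed = c(cond_instr, rep("none", 50L)),
        risky_side = risky_side,
        v_min = bp$v_min[lp],
        v_max = bp$v_max[lp]
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("trial_schedule", "data.frame")
    out
  })
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
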