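#' Stimulus items of an ordered list
#'
#' The task defines a list order over `n_items` stimuli, labelled with
#' consecutive letters starting at A. Rank 1 is the earliest item and is
#' correct against any later item; the last item is never rewarded.
#'
#' @param n_items Number of list items (default 7, the canonical design).
#' @return A data.frame with columns `label` and `rank`.
#' @export
#' @examples
#' ti_items(7)
ti_items <- function(n_items = 7) {
  if (!is.numeric(n_items) || length(n_items) != 1L || n_items < 2 ||
      n_items != round(n_items))
    stop("invalid design: n_items must be an integer >= 2", call. = FALSE)
  if (n_items > 26L)
    stop("invalid design: at most 26 items (letter labels)", call. = FALSE)
  n_items <- as.integer(n_items)
  data.frame(label = LETTERS[seq_len(n_items)], rank = seq_len(n_items),
             stringsAsFactors = FALSE)
}

#' All unordered stimulus pairs with their coordinates
#'
#' Every pair carries two orthogonal coordinates: symbolic distance (the
#' absolute rank difference) and joint rank (the rank sum). Over the full
#' design the map pair -> (distance, joint rank) is one-to-one, so the two
#' can be used together as predictors without collinearity.
#'
#' @inheritParams ti_items
#' @return A data.frame with one row per pair: `item_lo`, `item_hi`
#'   (earlier/later item labels), `rank_lo`, `rank_hi`, `distance`,
#'   `joint_rank`, and `pair` (concatenated labels, e.g. `"BD"`).
#' @export
#' @examples
#' nrow(all_pairs(7))  # 21
all_pairs <- function(n_items = 7) {
  items <- ti_items(n_items)
  idx <- utils::combn(nrow(items), 2L)
  lo <- idx[1L, ]
  hi <- idx[2L, ]
  out <- data.frame(
    item_lo = items$label[lo],
    item_hi = items$label[hi],
    rank_lo = items$rank[lo],
    rank_hi = items$rank[hi],
    distance = items$rank[hi] - items$rank[lo],
    joint_rank = items$rank[hi] + items$rank[lo],
    stringsAsFactors = FALSE
  )
  out$pair <- paste0(out$item_lo, out$item_hi)
  out[order(out$distance, out$joint_rank), , drop = FALSE]
}

#' Symbolic distance and joint rank of one pair
#'
#' @param pair Either a two-letter string (`"BD"`) or a character vector of
#'   two item labels.
#' @inheritParams ti_items
#' @return Named numeric vector `c(distance = , joint_rank = )`.
#' @export
#' @examples
#' pair_coordinates("BD")  # distance 2, joint rank 6
pair_coordinates <- function(pair, n_items = 7) {
  labs <- parse_pair(pair)
  items <- ti_items(n_items)
  r <- match(labs, items$label)
  if (anyNA(r))
    stop("invalid pair: unknown item label in '", paste(labs, collapse = ""),
         "'", call. = FALSE)
  if (labs[1L] == labs[2L])
    stop("invalid pair: the two items must differ", call. = FALSE)
  c(distance = abs(r[2L] - r[1L]), joint_rank = r[1L] + r[2L])
}

parse_pair <- function(pair) {
  if (is.character(pair) && length(pair) == 1L && nchar(pair) == 2L)
    pair <- strsplit(pair, "")[[1L]]
  if (!is.character(pair) || length(pair) != 2L)
    stop("invalid pair: supply a two-letter string or two labels",
         call. = FALSE)
  toupper(pair)
}

#' Stimulus pairs presented in each training phase
#'
#' Phase 1 masses the final pair of the list (FG in the 7-item design).
#' Phase 2 presents the adjacent pairs plus every pair containing one of
#' the two massed items (15 pairs for 7 items). Phase 3 presents all pairs.
#'
#' @param phase Phase id, 1, 2 or 3.
#' @inheritParams ti_items
#' @return A pair data.frame as returned by [all_pairs()], subset to the
#'   phase's pairs.
#' @export
phase_pairs <- function(phase, n_items = 7) {
  if (!phase %in% c(1L, 2L, 3L))
    stop("unknown phase id: ", phase, " (must be 1, 2 or 3)", call. = FALSE)
  pairs <- all_pairs(n_items)
  last_two <- LETTERS[c(n_items - 1L, n_items)]
  if (phase == 1) {
    pairs[pairs$item_lo == last_two[1L] & pairs$item_hi == last_two[2L], ,
          drop = FALSE]
  } else if (phase == 2) {
    keep <- pairs$distance == 1L |
      pairs$item_lo %in% last_two | pairs$item_hi %in% last_two
    pairs[keep, , drop = FALSE]
  } else {
    pairs
  }
}

#' Species-level design profile
#'
#' Monkeys complete 760-trial sessions (40 massed trials, then 20
#' presentations of each pair in phases 2 and 3: 40 + 300 + 420) over many
#' sessions with fresh stimuli each session. Humans complete one session of
#' half the length (20 + 150 + 210 = 380 trials).
#'
#' @param species `"monkey"` or `"human"`.
#' @param sessions_per_subject Sessions each subject completes (defaults:
#'   20 for monkeys, 1 for humans).
#' @param n_items Number of list items (default 7).
#' @return An object of class `"species_profile"`: a list with `name`,
#'   `n_items`, `presentations` (per-phase presentations per pair),
#'   `sessions_per_subject` and `session_trials`.
#' @export
#' @examples
#' species_profile("monkey")$session_trials  # 760
species_profile <- function(species = c("monkey", "human"),
                            sessions_per_subject = NULL, n_items = 7) {
  species <- match.arg(species)
  pres <- if (species == "monkey") c(40L, 20L, 20L) else c(20L, 10L, 10L)
  npairs <- vapply(1:3, function(p) nrow(phase_pairs(p, n_items)), 1L)
  prof <- list(
    name = species,
    n_items = as.integer(n_items),
    presentations = stats::setNames(pres, paste0("phase", 1:3)),
    sessions_per_subject = as.integer(
      sessions_per_subject %||% if (species == "monkey") 20L else 1L),
    phase_trials = stats::setNames(npairs * pres, paste0("phase", 1:3)),
    session_trials = sum(npairs * pres)
  )
  class(prof) <- "species_profile"
  prof
}

#' @export
print.species_profile <- function(x, ...) {
  cat("TI design profile:", x$name, "\n")
  cat("  items:", x$n_items, " session trials:", x$session_trials, "\n")
  cat("  presentations/pair by phase:",
      paste(x$presentations, collapse = " / "), "\n")
  cat("  trials by phase:", paste(x$phase_trials, collapse = " / "), "\n")
  cat("  sessions per subject:", x$sessions_per_subject, "\n")
  invisible(x)
}

#' Build one session's trial schedule
#'
#' Each phase's trials are a uniformly random permutation of that phase's
#' pair multiset (each pair repeated its presentation count). Within every
#' pair the correct item appears on the left on exactly half of its
#' presentations. Trial indices are 1-based and continuous across phases,
#' so phase 2 of the monkey design starts at trial 41.
#'
#' @param profile A [species_profile()].
#' @param seed Integer seed; the schedule is reproducible under it.
#' @return A data.frame of trial slots: `trial_index`, `phase`, `item_lo`,
#'   `item_hi`, `distance`, `joint_rank`, `pair`, `correct_side`.
#' @export
#' @examples
#' sched <- build_schedule(species_profile("human"), seed = 1)
#' nrow(sched)  # 380
build_schedule <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "species_profile"))
  with_seed(seed, {
    blocks <- lapply(1:3, function(ph) {
      pairs <- phase_pairs(ph, profile$n_items)
      reps <- profile$presentations[[ph]]
      if (reps %% 2L != 0L)
        stop("counterbalance error: presentations per pair must be even, ",
             "got ", reps, " in phase ", ph, call. = FALSE)
      slot <- pairs[rep(seq_len(nrow(pairs)), each = reps), , drop = FALSE]
      slot$correct_side <- rep(rep(c("left", "right"), each = reps / 2L),
                               times = nrow(pairs))
      slot[sample.int(nrow(slot)), , drop = FALSE]
    })
    out <- do.call(rbind, blocks)
    out$phase <- rep(1:3, times = vapply(blocks, nrow, 1L))
    out$trial_index <- seq_len(nrow(out))
    rownames(out) <- NULL
    out[, c("trial_index", "phase", "item_lo", "item_hi", "distance",
            "joint_rank", "pair", "correct_side")]
  })
}

#' Write a schedule to CSV
#'
#' @param schedule A schedule from [build_schedule()]; a `session` column is
#'   added (value `session`) if absent.
#' @param path Output file path.
#' @param session Session id used when the schedule has no session column.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path, session = 1L) {
  if (!"session" %in% names(schedule)) schedule$session <- session
  cols <- c("session", "trial_index", "phase", "item_lo", "item_hi",
            "distance", "joint_rank", "correct_side")
  utils::write.csv(schedule[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
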