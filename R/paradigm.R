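# Local-global auditory paradigm: blocks, series, tone timing, condition labels.

# Tone identities. A and B are binaural pure tones differing only in duration:
# A = 100 ms, B = 150 ms.
TONE_DURATION_MS <- c(A = 100, B = 150)

# Block-type assignments of global standard / global deviant series kinds.
# Block 2 reverses block 1, blocks 3-4 swap A and B. See ?build_block for the
# note on the reversal.
BLOCK_ASSIGNMENT <- list(
  `1` = list(standard = "AAAAB", deviant = "AAAAA"),
  `2` = list(standard = "AAAAA", deviant = "AAAAB"),
  `3` = list(standard = "BBBBB", deviant = "BBBBA"),
  `4` = list(standard = "BBBBA", deviant = "BBBBB")
)

#' Is a five-tone series locally deviant?
#'
#' A series is a local deviant when its fifth tone differs from the first four
#' (kinds AAAAB and BBBBA); AAAAA and BBBBB are local standards.
#'
#' @param kind Character vector of series kinds
#'   (`"AAAAA"`, `"AAAAB"`, `"BBBBB"`, `"BBBBA"`).
#' @return Logical vector.
#' @export
is_local_deviant <- function(kind) {
  stopifnot(all(kind %in% c("AAAAA", "AAAAB", "BBBBB", "BBBBA")))
  kind %in% c("AAAAB", "BBBBA")
}

#' Build one block of the local-global paradigm
#'
#' Generates the ordered series kinds for a single block. Each block presents
#' `n_standard` global-standard and `n_deviant` global-deviant series
#' (defaults 100 and 20, i.e. deviant probability 1/6). Deviant positions are
#' pseudo-random under two constraints: no two consecutive deviants, and no
#' deviant inside the initial run of standards (`lead_in` series, default 10)
#' so the global regularity can be established before it is violated.
#'
#' Block types: block 1 uses AAAAB as global standard and AAAAA as global
#' deviant; block 2 reverses that assignment; blocks 3 and 4 repeat the
#' structure with the tone roles swapped (block 3: standard BBBBB, deviant
#' BBBBA; block 4: standard BBBBA, deviant BBBBB). Note: the protocol text
#' describes block 2 as the reversal of block 1 while its parenthetical
#' example repeats block 1's order; the reversal is implemented here.
#'
#' @param block_type Integer 1-4.
#' @param seed Integer seed; the same `(block_type, seed)` always produces the
#'   same sequence.
#' @param n_standard,n_deviant Series counts per block.
#' @param lead_in Number of deviant-free series at the start of the block
#'   (capped at `n_standard` for small blocks).
#' @return A tibble with one row per series: `series_index`, `series_kind`,
#'   `global_label`, `local_label`, plus attributes `block_type`, `standard`,
#'   `deviant`.
#' @export
build_block <- function(block_type, seed,
                        n_standard = 100L, n_deviant = 20L,
                        lead_in = 10L) {
  if (length(block_type) != 1L || !block_type %in% 1:4) {
    stop("`block_type` must be a single integer in 1..4, got: ",
         deparse(substitute(block_type)), " = ", paste(block_type, collapse = ","))
  }
  n <- n_standard + n_deviant
  # cap the lead-in so small blocks keep a feasible non-adjacent placement
  lead_in <- max(0L, min(lead_in, n_standard, n - (2L * n_deviant - 1L)))
  asg <- BLOCK_ASSIGNMENT[[as.character(block_type)]]

  positions <- withr_seed(seed, sample_deviant_positions(n, n_deviant, lead_in))
  kinds <- rep(asg$standard, n)
  kinds[positions] <- asg$deviant

  out <- tibble::tibble(
    series_index = seq_len(n),
    series_kind = kinds,
    global_label = ifelse(seq_len(n) %in% positions, "deviant", "standard"),
    local_label = ifelse(is_local_deviant(kinds), "deviant", "standard")
  )
  attr(out, "block_type") <- as.integer(block_type)
  attr(out, "standard") <- asg$standard
  attr(out, "deviant") <- asg$deviant
  out
}

# Rejection-sample deviant positions: none in the first `lead_in` series and
# no two adjacent. Feasible whenever n - lead_in >= 2 * n_deviant - 1.
sample_deviant_positions <- function(n, n_deviant, lead_in) {
  if (n - lead_in < 2L * n_deviant - 1L) {
    stop("cannot place ", n_deviant, " non-adjacent deviants after a lead-in of ",
         lead_in, " in ", n, " series")
  }
  repeat {
    pos <- sort(sample((lead_in + 1L):n, n_deviant))
    if (n_deviant < 2L || all(diff(pos) > 1L)) return(pos)
  }
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a full session schedule
#'
#' Assembles 8 blocks (each of the 4 block types twice) in a semi-randomized
#' order — a random permutation in which the two repetitions of the same block
#' type are never adjacent — and lays the series out in time. Within a series
#' the five tone onsets are spaced by `soa_ms` (490 ms); the gap from each
#' fifth-tone onset to the next series' first-tone onset is drawn uniformly
#' from `iti_range_ms` (1450-1800 ms).
#'
#' @param seed Integer seed controlling block order, deviant placement and ITI
#'   draws.
#' @param n_standard,n_deviant Per-block series counts (defaults 100/20).
#' @param soa_ms Stimulus onset asynchrony between tones within a series.
#' @param iti_range_ms Length-2 numeric, inter-trial interval bounds in ms.
#' @param n_blocks Total block count (must be a multiple of 4; each type
#'   appears `n_blocks/4` times).
#' @return A `stimulus_schedule`: a tibble with one row per series — `block`,
#'   `block_type`, `series_index`, `series_kind`, `onset` (first-tone onset,
#'   seconds), `tone_onsets` (list-column of 5 onsets), `fifth_onset`,
#'   `global_label`, `local_label` — with attributes `soa_ms`, `iti_range_ms`,
#'   `seed`.
#' @examples
#' sched <- build_session(seed = 1)
#' dplyr::count(sched, global_label)
#' @export
build_session <- function(seed, n_standard = 100L, n_deviant = 20L,
                          soa_ms = 490, iti_range_ms = c(1450, 1800),
                          n_blocks = 8L) {
  stopifnot(n_blocks %% 4L == 0L, length(iti_range_ms) == 2L,
            iti_range_ms[1] <= iti_range_ms[2])
  reps <- n_blocks %/% 4L
  order <- withr_seed(child_seed(seed, "order"), semirandom_block_order(reps))

  blocks <- purrr::map2(order, seq_along(order), function(bt, i) {
    b <- build_block(bt, seed = child_seed(seed, "block", i),
                     n_standard = n_standard, n_deviant = n_deviant)
    dplyr::mutate(b, block = i, block_type = bt, .before = 1L)
  })
  sched <- dplyr::bind_rows(blocks)

  n <- nrow(sched)
  soa_s <- soa_ms / 1000
  itis <- withr_seed(child_seed(seed, "iti"),
                     stats::runif(n - 1L, iti_range_ms[1], iti_range_ms[2])) / 1000
  # onset of series i+1 = fifth-tone onset of series i + ITI_i
  onsets <- numeric(n)
  for (i in seq_len(n - 1L)) onsets[i + 1L] <- onsets[i] + 4 * soa_s + itis[i]
  sched$onset <- onsets
  sched$tone_onsets <- purrr::map(onsets, function(o) o + (0:4) * soa_s)
  sched$fifth_onset <- onsets + 4 * soa_s

  structure(sched,
            class = c("stimulus_schedule", class(sched)),
            soa_ms = soa_ms, iti_range_ms = iti_range_ms, seed = seed)
}

# Permutation of c(rep(1:4, reps)) with no equal adjacent entries.
semirandom_block_order <- function(reps) {
  types <- rep(1:4, reps)
  repeat {
    ord <- sample(types)
    if (!any(ord[-1] == ord[-length(ord)])) return(ord)
  }
}

#' Derive global and local condition labels for a schedule
#'
#' The two label dimensions are independent: the global label comes from the
#' block's standard/deviant series assignment, the local label only from the
#' series kind (deviant iff the fifth tone differs from the first four). In
#' block type 1 the global standards (AAAAB) are local deviants.
#'
#' @param schedule A `stimulus_schedule` (or any tibble with `series_kind`,
#'   `global_label` columns).
#' @return A tibble with `block`, `series_index`, `series_kind`,
#'   `global_label`, `local_label`.
#' @export
label_series <- function(schedule) {
  stopifnot(all(c("series_kind", "global_label") %in% names(schedule)))
  tibble::as_tibble(schedule)[, intersect(
    c("block", "series_index", "series_kind", "global_label"), names(schedule))] |>
    dplyr::mutate(local_label = ifelse(is_local_deviant(.data$series_kind),
                                       "deviant", "standard"))
}

#' Export / import a schedule as a BIDS-style events table
#'
#' Writes one row per series with columns `onset` (first-tone onset, s),
#' `duration` (first-to-fifth-tone span plus the fifth tone's duration, s),
#' `block`, `series_index`, `series_kind`, `global_label`, `local_label`,
#' plus a JSON sidecar (`<path>.json`) holding `soa_ms`, `iti_range_ms`,
#' `seed`.
#'
#' @param schedule A `stimulus_schedule`.
#' @param path Output path for the tab-separated events table.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  fifth_kind <- substr(schedule$series_kind, 5, 5)
  ev <- tibble::tibble(
    onset = schedule$onset,
    duration = 4 * attr(schedule, "soa_ms") / 1000 +
      TONE_DURATION_MS[fifth_kind] / 1000,
    block = schedule$block,
    series_index = schedule$series_index,
    series_kind = schedule$series_kind,
    global_label = schedule$global_label,
    local_label = schedule$local_label
  )
  readr::write_tsv(ev, path)
  sidecar <- list(soa_ms = attr(schedule, "soa_ms"),
                  iti_range_ms = attr(schedule, "iti_range_ms"),
                  seed = attr(schedule, "seed"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  soa_ms <- side$soa_ms %||% 490
  ev$tone_onsets <- purrr::map(ev$onset, function(o) o + (0:4) * soa_ms / 1000)
  ev$fifth_onset <- ev$onset + 4 * soa_ms / 1000
  structure(ev, class = c("stimulus_schedule", class(ev)),
            soa_ms = soa_ms,
            iti_range_ms = unlist(side$iti_range_ms) %||% c(1450, 1800),
            seed = side$seed)
}
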