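#' Roving-oddball paradigm configuration
#'
#' Constants of the stimulus sequence: 600 tones per block at a 600-ms
#' onset-to-onset interval (6 min per block), train lengths 3-11 with
#' lengths 3-7 four times as probable as 8-11, an F0 drawn uniformly from
#' the remaining grid values at every train change, and the first five
#' events of each block excluded from analysis.
#'
#' @param soa stimulus onset asynchrony in seconds (onset-to-onset).
#' @param block_len events per block.
#' @param train_len_range integer range of train lengths (first tone included).
#' @param short_weight,long_weight sampling weights for lengths 3-7 vs 8-11.
#' @param f0_grid fundamental-frequency grid in Hz.
#' @param n_blocks_per_condition blocks per harmonicity condition.
#' @param block_initial_exclusion events excluded at the start of each block.
#' @param changing_per_train if `TRUE`, the changing condition draws one new
#'   jitter pattern per stimulus train instead of per sound.
#' @return an object of class `paradigm_config`.
#' @export
paradigm_config <- function(soa = 0.600,
                            block_len = 600,
                            train_len_range = c(3L, 11L),
                            short_weight = 4,
                            long_weight = 1,
                            f0_grid = seq(500, 800, by = 50),
                            n_blocks_per_condition = 2,
                            block_initial_exclusion = 5,
                            changing_per_train = FALSE) {
  stopifnot(
    soa > 0, block_len >= max(train_len_range),
    short_weight > 0, long_weight > 0,
    length(f0_grid) >= 2, train_len_range[1] >= 1,
    train_len_range[2] >= train_len_range[1]
  )
  structure(
    list(
      soa = soa, block_len = as.integer(block_len),
      train_len_range = as.integer(train_len_range),
      short_weight = short_weight, long_weight = long_weight,
      f0_grid = f0_grid,
      n_blocks_per_condition = n_blocks_per_condition,
      block_initial_exclusion = as.integer(block_initial_exclusion),
      changing_per_train = changing_per_train
    ),
    class = "paradigm_config"
  )
}

train_length_support <- function(cfg) {
  lens <- cfg$train_len_range[1]:cfg$train_len_range[2]
  w <- ifelse(lens <= 7, cfg$short_weight, cfg$long_weight)
  list(lengths = lens, prob = w / sum(w))
}

#' Draw one train length
#'
#' Lengths 3-7 carry weight 4 and lengths 8-11 weight 1, i.e.
#' `P(L = l) = 4/24` for short and `1/24` for long trains
#' (`E[L] = 138/24 = 5.75`).
#'
#' @param cfg a [paradigm_config()].
#' @param n number of draws.
#' @return integer vector of train lengths.
#' @export
draw_train_length <- function(cfg = paradigm_config(), n = 1) {
  s <- train_length_support(cfg)
  sample(s$lengths, n, replace = TRUE, prob = s$prob)
}

#' Draw the next fundamental frequency
#'
#' Uniform over the grid values different from the current one, so the
#' implied shift magnitude lies in 50-300 Hz (both directions) on the
#' default 500-800 Hz grid.
#'
#' @param current current F0 in Hz (must be on the grid).
#' @param cfg a [paradigm_config()].
#' @return the next F0 in Hz.
#' @export
draw_next_f0 <- function(current, cfg = paradigm_config()) {
  if (!current %in% cfg$f0_grid) stop("current F0 not on grid: ", current)
  choices <- setdiff(cfg$f0_grid, current)
  if (length(choices) == 0L) stop("F0 grid has a single value; no roving possible")
  if (length(choices) == 1L) choices else sample(choices, 1)
}

#' Generate one roving-oddball block
#'
#' Draws trains until the block length is reached (the final train is
#' truncated), assigns F0s with no immediate repetition, and labels every
#' event: `deviant_order` 1-3 for the first three tones after an F0 change
#' (never in the block-initial train), `role` `"excluded"` for the first
#' five events of the block, `"deviant"` for labeled deviants, and
#' `"standard"` for tones at position >= 4 in their train. `shift_hz` is the
#' signed F0 change of the event's train relative to the previous train.
#'
#' Jitter-pattern assignment follows the condition: none for `"harmonic"`,
#' a single pattern for the whole block for `"inharmonic"`, and a fresh
#' pattern per sound for `"changing"` (per train if the config says so).
#'
#' @param condition `"harmonic"`, `"inharmonic"` or `"changing"`.
#' @param cfg a [paradigm_config()].
#' @param seed optional integer seed (block is deterministic given it).
#' @param pattern_source function `(n)` returning `n` jitter-pattern ids;
#'   defaults to opaque sequential ids. Pass a closure over
#'   [draw_jitter_pattern()] to tie the table to real synthesized patterns.
#' @return an `event_table` data.frame (see fields above) with the config
#'   stored in `attr(, "config")`.
#' @export
generate_block <- function(condition = c("harmonic", "inharmonic", "changing"),
                           cfg = paradigm_config(), seed = NULL,
                           pattern_source = NULL) {
  condition <- match.arg(condition)
  with_seed(seed, {
    # draw trains until cumulated length >= block_len, then truncate
    lens <- integer(0)
    total <- 0L
    while (total < cfg$block_len) {
      l <- draw_train_length(cfg)
      lens <- c(lens, l)
      total <- total + l
    }
    overshoot <- total - cfg$block_len
    if (overshoot > 0L) lens[length(lens)] <- lens[length(lens)] - overshoot

    n_trains <- length(lens)
    f0s <- numeric(n_trains)
    f0s[1] <- sample(cfg$f0_grid, 1)
    for (k in seq_len(n_trains - 1L)) f0s[k + 1] <- draw_next_f0(f0s[k], cfg)

    train_index <- rep(seq_len(n_trains), lens)
    position <- unlist(lapply(lens, seq_len), use.names = FALSE)
    f0 <- rep(f0s, lens)
    shift <- rep(c(NA, diff(f0s)), lens)

    deviant_order <- ifelse(train_index > 1L & position <= 3L, position, NA_integer_)
    idx <- seq_len(cfg$block_len)
    role <- ifelse(idx <= cfg$block_initial_exclusion, "excluded",
                   ifelse(!is.na(deviant_order), "deviant", "standard"))
    # block-initial train tones before position 4 that escaped the exclusion
    # window are neither standards nor deviants; with min train length 3 and
    # 5 excluded events this is unreachable, but guard anyway
    role[train_index == 1L & position < 4L & role == "standard"] <- "excluded"

    pattern_id <- rep(NA_character_, cfg$block_len)
    if (condition != "harmonic") {
      n_pat <- switch(condition,
        inharmonic = 1L,
        changing = if (cfg$changing_per_train) n_trains else cfg$block_len
      )
      ids <- if (is.null(pattern_source)) {
        # opaque but unique placeholder ids (a real pattern source supplies
        # ids tied to synthesized jitter patterns)
        sprintf("jp-%08x-%04d", sample.int(.Machine$integer.max, 1), seq_len(n_pat))
      } else {
        pattern_source(n_pat)
      }
      pattern_id <- switch(condition,
        inharmonic = rep(ids, cfg$block_len),
        changing = if (cfg$changing_per_train) rep(ids, lens) else ids
      )
    }

    tab <- data.frame(
      index = idx,
      onset = (idx - 1L) * cfg$soa,
      f0 = f0,
      condition = condition,
      pattern_id = pattern_id,
      train_index = train_index,
      position_in_train = position,
      deviant_order = deviant_order,
      role = role,
      shift_hz = shift,
      stringsAsFactors = FALSE
    )
    attr(tab, "config") <- cfg
    class(tab) <- c("event_table", "data.frame")
    tab
  })
}

#' Duration of a block in seconds
#'
#' Under the onset-to-onset reading of the stimulation interval the block
#' occupies `n_events * soa` seconds (600 events at 0.6 s = 6 min).
#'
#' @param table an `event_table`, or an event count.
#' @param cfg a [paradigm_config()].
#' @return duration in seconds.
#' @export
block_duration <- function(table, cfg = paradigm_config()) {
  n <- if (is.data.frame(table)) nrow(table) else as.integer(table)
  n * cfg$soa
}

#' Write an event table to CSV with a JSON config sidecar
#'
#' @param table an `event_table`.
#' @param path CSV output path; a `.json` sidecar with the paradigm config
#'   and seed is written next to it.
#' @param seed seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(table, path, seed = NULL) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  cfg <- attr(table, "config")
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(config = cfg[setdiff(names(cfg), "class")], seed = seed),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
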