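#' Generate a roving-oddball tone sequence
#'
#' Emulates the stimulus structure of the roving auditory oddball paradigm:
#' tone frequency steps up or down by 50 Hz on a 400-800 Hz grid after 3 to
#' 10 repetitions (train lengths uniform on 3..10). The first tone of every
#' train after the first is labelled `deviant`; the sixth tone of a train
#' is labelled `standard`; all other tones are `other`.
#'
#' @param n_tones number of tones to emit (the final train may be
#'   truncated).
#' @param seed RNG seed.
#' @return tibble with `tone` (index), `freq_hz`, `train`, `position`,
#'   `label`.
#' @export
generate_roving_sequence <- function(n_tones, seed = 1) {
  if (n_tones < 1) abort("`n_tones` must be >= 1")
  grid <- seq(400, 800, by = 50)
  with_local_seed(seed, {
    # generate whole trains until enough tones, then truncate
    freqs <- integer(0); train <- integer(0); pos <- integer(0)
    f <- sample(grid, 1)
    tr <- 0L
    while (length(freqs) < n_tones) {
      tr <- tr + 1L
      len <- sample(3:10, 1)
      freqs <- c(freqs, rep(f, len))
      train <- c(train, rep(tr, len))
      pos <- c(pos, seq_len(len))
      # next frequency: +/- 50 Hz, reflected at the range limits
      step <- if (f <= 400) 50 else if (f >= 800) -50 else
        sample(c(-50, 50), 1)
      f <- f + step
    }
    idx <- seq_len(n_tones)
    label <- rep("other", n_tones)
    label[pos[idx] == 1L & train[idx] > 1L] <- "deviant"
    label[pos[idx] == 6L] <- "standard"
    tibble::tibble(tone = idx, freq_hz = freqs[idx], train = train[idx],
                   position = pos[idx], label = label)
  })
}
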