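# Shared fixtures: a reduced filter bank for fast tests and a bar-stimulus
# helper. The reduced bank keeps the bank's structure (several orientations
# x several scales) at a fraction of the default channel count.

small_bank_spec <- function() filter_bank_spec(n_orientations = 8, sigmas = c(1, 2))

small_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- build_filter_bank(small_bank_spec())
    bank
  }
})

default_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- build_filter_bank()
    bank
  }
})

bar_image <- function(angle, length = 20, width = 3, grid = c(28, 28)) {
  render_strokes(list(list(angle = angle, length = length, width = width)),
                 grid = grid)
}
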