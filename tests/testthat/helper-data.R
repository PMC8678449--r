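# Small in-code fixtures shared across test files.

make_ds <- function(counts, date = as.Date("2020-06-11"),
                    instar = "combined", site = "A") {
  trap_data(data.frame(
    site = site, plot = paste0("p", seq_along(counts)),
    trap_id = paste0("t", seq_along(counts)),
    date = date, instar = instar, count = as.integer(counts),
    stringsAsFactors = FALSE))
}

# One date per element of `count_list`, same traps throughout.
make_series_ds <- function(count_list, start = as.Date("2020-06-11"),
                           step = 3) {
  rows <- lapply(seq_along(count_list), function(i) {
    counts <- count_list[[i]]
    data.frame(site = "A", plot = paste0("p", seq_along(counts)),
               trap_id = paste0("t", seq_along(counts)),
               date = start + (i - 1) * step, instar = "combined",
               count = as.integer(counts), stringsAsFactors = FALSE)
  })
  trap_data(do.call(rbind, rows))
}
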