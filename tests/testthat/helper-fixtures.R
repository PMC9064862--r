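# Small simulation configurations for fast unit tests. The full study
# conditions live in demo_config() and are exercised by the acceptance
# tests.

tiny_plan <- function() {
  data.frame(
    bgc_id = c("t_terp", "t_bact"),
    class = c("terpene", "bacteriocin"),
    length_bp = c(5400L, 3600L),
    transporter = c(FALSE, FALSE),
    stringsAsFactors = FALSE)
}

tiny_config <- function(seed = 7L, ...) {
  defaults <- list(n_fragments = 2, fragment_len = c(60000, 61000),
                   n_clones = 12, pool_size = 5,
                   insert_len = c(30000, 35000), long_read_coverage = 6,
                   bgc_plan = tiny_plan(), seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
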