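# Expand per-species cohort counts (the printed summary-table shape)
# into the record-level tables summarize_cohort() consumes.
expand_cohort_fixture <- function(path) {
  tab <- utils::read.csv(path)
  flights <- list(); deps <- list(); landings <- character(0)
  for (i in seq_len(nrow(tab))) {
    n_fl <- tab$onshore[i] + tab$offshore[i]
    years <- rep(c(2019L, 2020L, 2021L),
                 times = c(tab$y2019[i], tab$y2020[i], tab$y2021[i]))
    stopifnot(length(years) == n_fl)
    ids <- sprintf("%s_%03d", substr(tab$species[i], 1, 2), seq_len(n_fl))
    flights[[i]] <- data.frame(
      tag_id = ids, year = years,
      route = rep(c("onshore", "offshore"),
                  times = c(tab$onshore[i], tab$offshore[i])))
    landings <- c(landings, ids[seq_len(tab$landings[i])])
    deps[[i]] <- data.frame(
      tag_id = c(ids, sprintf("%s_x%03d", substr(tab$species[i], 1, 2),
                              seq_len(tab$n_tagged[i] - n_fl))),
      species = tab$species[i])
  }
  list(flights = do.call(rbind, flights),
       landings = data.frame(tag_id = landings),
       deployments = do.call(rbind, deps))
}
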