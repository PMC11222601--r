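# Build the packaged consensus-score fixture CSVs from their published
# transition counts (see clinical_fixtures() docs).
make <- function(prefix, transitions, truth) {
  rows <- do.call(rbind, lapply(transitions, function(tr) {
    data.frame(score_dsa = rep(tr[1], tr[3]), score_combined = rep(tr[2], tr[3]))
  }))
  rows$case_id <- sprintf("%s%03d", prefix, seq_len(nrow(rows)))
  rows$truth <- truth
  rows[, c("case_id", "score_dsa", "score_combined", "truth")]
}
bleeding <- make("B", list(c(5,5,46), c(4,5,28), c(4,4,20), c(3,4,7)), "bleeding")
no_bleeding <- make("N", list(c(1,1,21), c(2,1,13)), "no_bleeding")
ex_vivo <- make("E", list(c(5,5,11), c(4,5,7), c(4,3,2), c(3,5,1), c(3,4,1)), "unknown")
stopifnot(nrow(bleeding) == 101, nrow(no_bleeding) == 34, nrow(ex_vivo) == 22)
out <- file.path("inst", "extdata")
write.csv(bleeding, file.path(out, "bleeding_scores.csv"), row.names = FALSE, quote = FALSE)
write.csv(no_bleeding, file.path(out, "no_bleeding_scores.csv"), row.names = FALSE, quote = FALSE)
write.csv(ex_vivo, file.path(out, "ex_vivo_scores.csv"), row.names = FALSE, quote = FALSE)
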