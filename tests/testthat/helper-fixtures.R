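# Synthetic fixture files in the layout of the UCI tables (tiny, written at
# test time; these are NOT the real yeast/pendigits/isolet data).

write_yeast_fixture <- function(path, n = 40) {
  set.seed(31)
  classes <- c("CYT", "NUC", "MIT")
  lines <- vapply(seq_len(n), function(i) {
    feats <- sprintf("%.2f", runif(8))
    paste(c(sprintf("SEQ%04d", i), feats,
            classes[1 + (i %% 3)]), collapse = "  ")
  }, "")
  writeLines(lines, path)
}

write_digits_fixture <- function(path, n = 30, D = 16, K = 10) {
  set.seed(32)
  M <- cbind(matrix(round(runif(n * D) * 100), n, D),
             sample(0:(K - 1), n, replace = TRUE))
  write.table(M, path, sep = ",", row.names = FALSE, col.names = FALSE)
}
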