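# Shared small fixtures built in code.

# Well-separated blob cohort for clustering tests.
blob_cohort <- function(n = 60, k = 3, p = 200, delta = 3, seed = 42) {
  generate_cohort(n = n, p = p, k = k, g = min(p, max(20, p %/% 5)),
                  delta = delta, censor_rate = 0.3, seed = seed)
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
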