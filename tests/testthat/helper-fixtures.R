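# shared fixtures: built in code, no files shipped

make_rep <- function(counts, sample_id = "s", population = "P") {
  repertoire(counts, sample_id = sample_id, population = population)
}

# minimal valid clonotype table rows; cdr3 strings derived from the key letter
clono_rows <- function(sample_id, population, keys, counts) {
  nt <- vapply(keys, function(k) {
    paste(rep(c(A = "GCA", B = "TGC", C = "TGT", D = "GAT", E = "GAA",
                F = "TTC", G = "GGA", H = "CAC")[k], 5), collapse = "")
  }, character(1))
  data.frame(sample_id = sample_id, population = population,
             v_gene = paste0("TRAV", match(keys, LETTERS)),
             j_gene = "TRAJ1",
             cdr3_nt = nt,
             cdr3_aa = paste0("CA", keys, "F"),
             count = counts, stringsAsFactors = FALSE)
}

write_clono_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

peak_rows <- function(sample_id, population, trbv, lengths, areas) {
  data.frame(sample_id = sample_id, population = population, trbv = trbv,
             cdr3_length = lengths, area = areas, stringsAsFactors = FALSE)
}

write_peak_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  path
}

# a random normalized frequency vector on the given integer support
random_profile <- function(lengths) {
  w <- rgamma(length(lengths), shape = 1)
  setNames(w / sum(w), as.character(lengths))
}

# spectratype sample object built directly (bypassing file IO)
make_spectra <- function(profiles, sample_id = "s", population = "P") {
  structure(list(sample_id = sample_id, population = population,
                 profiles = profiles),
            class = "sample_spectratype")
}

make_reference <- function(profiles, label = "ref") {
  structure(list(label = label, profiles = profiles),
            class = "reference_spectratype")
}
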