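# shared fixtures: small compound tables written on the fly

write_fixture_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# 3-row standard table with mixed label vocabulary and one bad numeric cell
fixture_standard <- function() {
  write_fixture_csv(c(
    "id,smiles,charge,bbb,ccs,mw,xlogp3",
    "d1,CCO,neutral,BBB+,174.2,180.1,0.5",
    "d2,CCN,positive,cns-,215.9,310.4,-1.5",
    "d3,CCC,negative,1,n/a,95.0,2.0"
  ))
}

tiny_dataset <- function(ccs = c(150, 190, 210, 260),
                         labels = c("BBB+", "BBB+", "BBB-", "BBB-")) {
  compound_dataset(data.frame(
    id = paste0("c", seq_along(ccs)),
    ccs = ccs, bbb_label = labels, stringsAsFactors = FALSE), name = "tiny")
}

# a dataset where ccs carries all the class signal and the rest is noise
signal_only_ccs <- function(n_per_class = 150, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  df <- data.frame(
    id = paste0("s", seq_len(n)),
    bbb_label = rep(c("BBB_plus", "BBB_minus"), each = n_per_class),
    ccs = c(rnorm(n_per_class, 170, 20), rnorm(n_per_class, 240, 20)))
  for (d in c("logd74", "h_acceptors", "h_donors",
              "rotatable_bonds", "pka")) {
    df[[d]] <- rnorm(n)
  }
  for (d in c("mw", "psa")) df[[d]] <- abs(rnorm(n, 100, 10))  # label-free noise
  compound_dataset(df, name = "signal_only_ccs")
}
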