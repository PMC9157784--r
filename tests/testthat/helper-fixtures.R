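# Shared fixtures: printed survey summary rows and small hand-built
# incidence matrices.

# Published per-survey counts: sample size, uniques, duplicates, observed
# richness, the reported estimate (with variant and CI) and effort columns.
table2_rows <- function() {
  read.csv(text = "site,year,m,incidences,Sobs,Q1,Q2,variant,sest,ci_lo,ci_hi,s95,s100
StJoseph,2017,59,258,28,6,4,classic,32.4,28.8,52.5,44,171
Saginaw,2018,60,498,41,11,4,classic,55.9,44.6,102.1,136,426
Cleveland,2017,69,232,24,5,3,classic,28.1,24.7,49.4,61,214
Cleveland,2019,55,272,26,7,4,classic,32.0,27.2,56.5,63,202
Detroit,2018,39,409,34,3,6,bias_corrected,34.4,34.0,39.5,NA,24
Detroit,2019,39,480,39,7,4,classic,45.0,40.2,69.3,33,143
Milwaukee,2017,73,105,16,6,1,bias_corrected,23.4,17.3,58.0,509,1151
Milwaukee,2018,65,265,26,7,5,classic,30.8,27.0,50.4,52,182
Milwaukee,2019,58,177,25,8,2,classic,40.7,28.0,108.4,234,598
Cleveland,all,125,506,30,6,3,bias_corrected,33.7,30.6,51.9,149,515
Detroit,all,78,889,43,4,3,bias_corrected,44.5,43.2,55.3,7,169
Milwaukee,all,196,547,34,8,6,classic,39.3,35.1,58.8,130,536",
           stringsAsFactors = FALSE)
}

counts_for <- function(row) {
  incidence_counts(row$m, Sobs = row$Sobs, Q1 = row$Q1, Q2 = row$Q2,
                   incidences = row$incidences)
}

# random incidence matrix with controllable size
random_matrix <- function(m, S, p = 0.4, species = NULL) {
  pres <- matrix(runif(m * S) < p, m, S,
                 dimnames = list(paste0("u", seq_len(m)), paste0("sp", seq_len(S))))
  incidence_matrix(pres, species = species)
}

# a frequency vector realised as a concrete matrix (frequencies = colSums)
matrix_with_frequencies <- function(freq, m) {
  stopifnot(all(freq <= m))
  pres <- sapply(freq, function(f) {
    v <- rep(FALSE, m); v[sample.int(m, f)] <- TRUE; v
  })
  rownames(pres) <- paste0("u", seq_len(m))
  colnames(pres) <- paste0("sp", seq_along(freq))
  incidence_matrix(pres)
}

small_species <- function(codes, origin = NULL) {
  species_table(data.frame(
    code = codes,
    origin = if (is.null(origin)) rep("native", length(codes)) else origin,
    stringsAsFactors = FALSE))
}
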