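library(data.table)

# compact constructor for CpG call tables
make_calls <- function(chrom, pos, n_meth, n_unmeth) {
  data.table(chrom = chrom, pos = as.integer(pos),
             n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))
}

# a small synthetic genome that keeps simulation-heavy tests fast
tiny_spec <- function(...) {
  args <- list(chrom_sizes = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
               n_iap = 60, n_line = 80, n_sine = 100, n_rare = 30,
               n_satellite = 60, n_lost = 40, n_fgo_only = 30, n_genes = 10)
  do.call(synthetic_genome_spec, utils::modifyList(args, list(...)))
}

# brute-force weighted level over sites with pos-1 in [start, end)
oracle_interval_level <- function(calls, chrom_, start_, end_) {
  s <- calls[chrom == chrom_ & pos - 1 >= start_ & pos - 1 < end_]
  if (nrow(s) == 0) return(NA_real_)
  sum(s$n_meth) / sum(s$n_meth + s$n_unmeth)
}

# random calls on one chromosome, uniform positions, arbitrary counts
random_calls <- function(n, chrom = "chr1", max_pos = 1e6, max_depth = 30) {
  pos <- sort(sample.int(max_pos, n))
  d <- sample.int(max_depth, n, replace = TRUE)
  m <- rbinom(n, d, runif(n))
  make_calls(chrom, pos, m, d - m)
}
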