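# Shared builders for small in-memory profiles.

withr_local_tempfile <- function(ext = "") {
  withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
}

ref <- mitotempo::synthetic_reference()

# alternate base guaranteed to differ from the reference at `pos`
alt_base <- function(pos) {
  bases <- c("A", "C", "G", "T")
  vapply(ref$bases[pos], function(b) bases[(match(b, bases) %% 4L) + 1L], "")
}

# substitution-only profile at the given positions (alt = next base in
# ACGT order after the reference base, so it always differs)
sub_profile <- function(id, positions, age = -50, hap = "H", macro = "R") {
  positions <- as.integer(positions)
  v <- if (length(positions)) {
    refb <- ref$bases[positions]
    alt <- vapply(refb, function(b) {
      bases <- c("A", "C", "G", "T")
      bases[(match(b, bases) %% 4L) + 1L]
    }, "")
    mitotempo::variant_table(positions, refb, alt, "substitution")
  } else {
    mitotempo::variant_table()
  }
  mitotempo::mito_profile(id, age, hap, macro, v)
}

# haplogroup sample whose members carry `counts[i]` substitutions each,
# relative to an empty root haplotype (positions below 16,000 so no
# exclusion applies)
counts_sample <- function(counts, label = "H") {
  members <- lapply(seq_along(counts), function(i) {
    k <- counts[i]
    sub_profile(paste0("m", i), if (k > 0) seq_len(k) else integer())
  })
  mitotempo::haplogroup_sample(label, members = members)
}
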