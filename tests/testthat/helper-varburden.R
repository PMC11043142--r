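# Shared fixtures and independent oracles used across the suite.

fixture_path <- function() {
  system.file("extdata", "otog_fmd_variants.tsv", package = "varburden")
}

load_fmd_table <- function() {
  read_variant_table(fixture_path())
}

# --- independent oracles ----------------------------------------------------

# Two-sided Fisher p by full enumeration over tables with both margins fixed,
# probabilities from choose() products (independent of dhyper).
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  xs <- max(0, k - r2):min(k, r1)
  probs <- choose(r1, xs) * choose(r2, k - xs) / choose(n, k)
  p_obs <- choose(r1, a) * choose(r2, k - a) / choose(n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up by direct definition:
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Region segmentation by a per-position loop (no rle), returning the same
# 0-based half-open layout as call_regions().
regions_oracle <- function(density, threshold) {
  lab <- ifelse(density < threshold, "LDR", "HDR")
  starts <- integer(0); ends <- integer(0); labs <- character(0)
  cur <- lab[1]; s <- 0L
  for (i in seq_along(lab)[-1]) {
    if (lab[i] != cur) {
      starts <- c(starts, s); ends <- c(ends, i - 1L); labs <- c(labs, cur)
      cur <- lab[i]; s <- i - 1L
    }
  }
  data.frame(start = c(starts, s), end = c(ends, length(lab)),
             label = c(labs, cur), stringsAsFactors = FALSE)
}

# Jaccard overlap of [s1,e1) and [s2,e2) interval pairs (bp).
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  inter / union
}

# Best Jaccard between a planted segment and any called LDR region.
best_ldr_jaccard <- function(regions, seg_start, seg_end) {
  ldr <- regions[regions$label == "LDR", , drop = FALSE]
  if (nrow(ldr) == 0) return(0)
  max(vapply(seq_len(nrow(ldr)), function(k) {
    interval_jaccard(ldr$start[k], ldr$end[k], seg_start, seg_end)
  }, numeric(1)))
}

# Hand-built region_set for similarity / annotation tests.
make_regions <- function(start, end, label, cds_length, population = NA) {
  structure(
    tibble::tibble(start = as.integer(start), end = as.integer(end),
                   label = label,
                   mean_density = rep(NA_real_, length(start))),
    class = c("region_set", class(tibble::tibble())),
    population = population, cds_length = as.integer(cds_length),
    threshold = NA_real_
  )
}

# --- tiny VCF fixture writer ------------------------------------------------

write_sites_vcf <- function(path, rows, pops = c("NFE", "AFR")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=NC_000011.10>",
    unlist(lapply(pops, function(p) c(
      sprintf("##INFO=<ID=AF_%s,Number=A,Type=Float,Description=\"AF\">", p),
      sprintf("##INFO=<ID=AC_%s,Number=A,Type=Integer,Description=\"AC\">", p),
      sprintf("##INFO=<ID=AN_%s,Number=1,Type=Integer,Description=\"AN\">", p)
    ))),
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"consequence\">",
    "##INFO=<ID=CDS_POS,Number=A,Type=Integer,Description=\"CDS position\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  writeLines(c(hdr, rows), path)
}
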