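# In-code fixtures shared across test files.

# A small fixed lineage pool with shared prefixes at several depths, plus a
# partial lineage, used to stress consensus depth.
fixture_lineage_pool <- function() {
  c("Bacteria;Pseudomonadota;Gammaproteobacteria;Vibrionales;Vibrionaceae;Vibrio;Vibrio cholerae",
    "Bacteria;Pseudomonadota;Gammaproteobacteria;Vibrionales;Vibrionaceae;Vibrio;Vibrio vulnificus",
    "Bacteria;Pseudomonadota;Gammaproteobacteria;Vibrionales;Vibrionaceae;Photobacterium;Photobacterium damselae",
    "Bacteria;Pseudomonadota;Gammaproteobacteria;Alteromonadales;Shewanellaceae;Shewanella;Shewanella baltica",
    "Bacteria;Pseudomonadota;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae;Ruegeria;Ruegeria pomeroyi",
    "Bacteria;Chloroflexota;Dehalococcoidia;SAR202;;;",
    "Bacteria;Nitrospirota;Nitrospiria;Nitrospirales;Nitrospiraceae;Nitrospira;Nitrospira marina",
    "Archaea;Thermoproteota;Nitrososphaeria;Nitrosopumilales;Nitrosopumilaceae;Nitrosopumilus;Nitrosopumilus maritimus")
}

# One random query's hit set. With coupled = TRUE percent identity is
# rank-matched to bitscore (higher score never has lower identity), the
# regime real alignment scores live in; with coupled = FALSE the two are
# independent, a harsher stress for oracle-equivalence checks.
random_hitset <- function(query_id = "q1", coupled = FALSE,
                          include_missing = TRUE) {
  pool <- fixture_lineage_pool()
  n <- sample(1:12, 1)
  bitscore <- round(runif(n, 60, 900), 1)
  pident <- round(runif(n, 60, 100), 1)
  if (coupled) pident <- sort(pident)[rank(bitscore, ties.method = "first")]
  lineage <- sample(pool, n, replace = TRUE)
  if (include_missing && n > 2 && runif(1) < 0.2) lineage[1] <- NA
  data.frame(query_id = query_id,
             subject_id = sprintf("s%02d", seq_len(n)),
             pct_identity = pident,
             alignment_length = sample(20:500, n, replace = TRUE),
             evalue = 10^runif(n, -80, -6),
             bitscore = bitscore,
             lineage = lineage,
             lineage_missing = is.na(lineage),
             stringsAsFactors = FALSE)
}

# A tiny deterministic count table: 5 OTUs x (4 true samples + 2 controls).
fixture_otu_table <- function() {
  counts <- matrix(c(500, 480, 510, 490,  50, 45,   # contaminant-like anchor
                     120, 100,  90, 110,  10, 12,   # scaled contaminant
                     300,   0, 250,  40,   0,  0,   # clean, patchy
                      80,  70,  60,  90,   0,  0,   # clean, ubiquitous
                       0,   0,   0,   0,  30, 25),  # control-only
                   nrow = 5, byrow = TRUE,
                   dimnames = list(paste0("otu", 1:5),
                                   c("A", "B", "C", "D", "N1", "N2")))
  otu_table(counts, c(A = "true_sample", B = "true_sample",
                      C = "true_sample", D = "true_sample",
                      N1 = "field_control", N2 = "pcr_control"))
}

write_hit_file <- function(hits, path) {
  out <- data.frame(hits$query_id, hits$subject_id, hits$pct_identity,
                    hits$alignment_length, 0L, 0L, 1L, hits$alignment_length,
                    1L, hits$alignment_length,
                    format(hits$evalue, scientific = TRUE), hits$bitscore)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}
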