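# Frozen per-stage record counts of the full pipeline on the canonical
# seed-7 fixture, established by the initial oracle run and frozen.
frozen_fixture_manifest <- function() {
  tibble::tribble(
    ~stage, ~count,
    "catalog_edges", 2686L,
    "global_tested_pairs", 14546L,
    "global_significant_pairs", 48L,
    "global_triplets", 321L,
    "colon_M0N_de_lncrna", 37L,
    "colon_M0N_de_mirna", 36L,
    "colon_M0N_de_mrna", 74L,
    "colon_M0N_candidates", 229L,
    "colon_M0N_triplets", 229L,
    "colon_M0N_nodes", 111L,
    "colon_M0N_lnc_biomarkers", 2L,
    "colon_M0N_mir_biomarkers", 2L,
    "colon_M0N_key_triplets", 4L,
    "rectal_M0N_de_lncrna", 35L,
    "rectal_M0N_de_mirna", 36L,
    "rectal_M0N_de_mrna", 78L,
    "rectal_M0N_candidates", 226L,
    "rectal_M0N_triplets", 226L,
    "rectal_M0N_nodes", 110L,
    "rectal_M0N_lnc_biomarkers", 2L,
    "rectal_M0N_mir_biomarkers", 2L,
    "rectal_M0N_key_triplets", 4L,
    "colon_M1N_de_lncrna", 32L,
    "colon_M1N_de_mirna", 36L,
    "colon_M1N_de_mrna", 89L,
    "colon_M1N_candidates", 187L,
    "colon_M1N_triplets", 181L,
    "colon_M1N_nodes", 92L,
    "colon_M1N_lnc_biomarkers", 1L,
    "colon_M1N_mir_biomarkers", 2L,
    "colon_M1N_key_triplets", 2L,
    "rectal_M1N_de_lncrna", 36L,
    "rectal_M1N_de_mirna", 36L,
    "rectal_M1N_de_mrna", 83L,
    "rectal_M1N_candidates", 200L,
    "rectal_M1N_triplets", 200L,
    "rectal_M1N_nodes", 108L,
    "rectal_M1N_lnc_biomarkers", 2L,
    "rectal_M1N_mir_biomarkers", 2L,
    "rectal_M1N_key_triplets", 2L,
    "common_de_lncrna", 27L,
    "common_de_mirna", 36L,
    "common_de_mrna", 50L,
    "shared_triplets", 127L
  )
}

# small planted configuration used where the full fixture would be slow
small_planted_config <- function(seed, n_normal = 10L, n_m0 = 10L,
                                 n_m1 = 5L) {
  synthetic_config(
    seed = seed, n_mirna = 40L, n_lncrna = 20L, n_mrna = 60L,
    n_normal = n_normal, n_m0 = n_m0, n_m1 = n_m1,
    n_nsm_lncrnas = 1L, nsm_partners = 3L, n_bg_pairs = 4L,
    n_nsr_pairs = 2L, n_extra_de = 10L
  )
}

# write a delimited interaction table for catalog-reading tests
write_toy_table <- function(df, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  readr::write_delim(df, path, delim = if (ext == "csv") "," else "\t")
  path
}
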