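# small in-code fixtures shared by several test files

tiny_counts <- function() {
  m <- matrix(c(5L, 0L, 3L,
                2L, 7L, 1L,
                4L, 4L, 9L), nrow = 3, byrow = TRUE,
              dimnames = list(c("F0001", "F0002", "A0001"),
                              c("s1", "s2", "s3")))
  count_table(m, data.frame(
    id = rownames(m), name = c("Fungus a", "Fungus b", "Archaeon c"),
    domain = c("fungal", "fungal", "archaeal"), stringsAsFactors = FALSE
  ))
}

# metadata frame for n samples spread over plates/dates
make_meta <- function(sample_ids, n_plates = 4, n_dates = 4,
                      tissue = NULL) {
  n <- length(sample_ids)
  if (is.null(tissue)) tissue <- rep("tumor", n)
  data.frame(
    sample_id = sample_ids,
    patient_id = paste0("P", seq_len(n)),
    tissue = tissue,
    subtype = ifelse(tissue == "tumor", "CPTC", NA_character_),
    gender = rep(c("male", "female"), length.out = n),
    seq_date = as.Date("2011-01-15") + 30 * (seq_len(n) %% n_dates),
    seq_plate = sprintf("plate%02d", (seq_len(n) %% n_plates) + 1L),
    braf_v600e = ifelse(tissue == "tumor", "negative", NA_character_),
    vital_status = NA_character_, perineural_invasion = NA_character_,
    pathologic_stage = NA_character_, t_stage = NA_character_,
    n_stage = NA_character_, m_stage = NA_character_,
    stringsAsFactors = FALSE
  )
}

# a small, fast simulation configuration for unit tests
quick_config <- function(seed = 7, ...) {
  simulation_config(
    n_tumor = 60, n_normal = 30, n_taxa_fungal = 80, n_taxa_archaeal = 20,
    n_dates = 8, n_plates = 8,
    contaminants = c(slope = 8, plate = 5, date = 5),
    da_effects = data.frame(cohort = "tumor", n = 5, lfc = 2,
                            direction = "up", stringsAsFactors = FALSE),
    clinical_effects = data.frame(variable = "pathologic_stage",
                                  level = "III|IV", n = 2, lfc = 2,
                                  stringsAsFactors = FALSE),
    expression = list(n_genes = 60, set_size = 8, target_cor = 0.8,
                      n_null_sets = 2, null_set_size = 8),
    seed = seed, ...
  )
}
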