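# Shared fixtures: packaged configuration loaded once, a tiny hand-built
# record set, and a random-case generator used by the engine-vs-oracle tests.

the_catalog <- load_catalog()
the_registry <- load_registry()
the_lexicon <- load_lexicon(registry = the_registry)
the_rules <- load_rule_base()

utc <- function(x) as.POSIXct(x, tz = "UTC")

# one three-day episode with temperature chart, labs, notes, an order and an
# operation; admission Jan 1 10:00, discharge Jan 3 11:00
tiny_records <- function() {
  new_records(
    admissions = data.frame(
      patient_id = "P1", episode_id = "E1",
      admission_datetime = utc("2020-01-01 10:00:00"),
      discharge_datetime = utc("2020-01-03 11:00:00"),
      age = 70, gender = 1, department = "respiratory",
      stringsAsFactors = FALSE),
    vitals = data.frame(
      episode_id = "E1",
      datetime = utc(c("2020-01-01 08:00:00", "2020-01-01 16:00:00",
                       "2020-01-02 09:00:00", "2020-01-02 17:30:00")),
      measure_id = "body_temperature",
      value = c(36.8, 38.9, 37.1, 39.2), stringsAsFactors = FALSE),
    labs = data.frame(
      episode_id = "E1",
      datetime = utc(c("2020-01-01 11:00:00", "2020-01-01 15:00:00",
                       "2020-01-02 09:00:00")),
      test_id = c("CRP", "CRP", "PLEURAL_WBC"),
      value = c(5, 42, 1500), unit = c("mg/L", "mg/L", "10^6/L"),
      abnormal_flag = c(0, 1, 1), stringsAsFactors = FALSE),
    micro = data.frame(
      episode_id = "E1", datetime = utc("2020-01-02 12:00:00"),
      specimen = "pleural_fluid", organism = "Escherichia coli",
      positive_flag = 1, stringsAsFactors = FALSE),
    notes = data.frame(
      episode_id = "E1",
      datetime = utc(c("2020-01-01 12:00:00", "2020-01-02 08:00:00")),
      note_type = c("progress", "imaging"),
      text = c("Patient reports chest pain since last night.",
               "Right-sided pleural effusion is seen."),
      stringsAsFactors = FALSE),
    operations = data.frame(
      episode_id = "E1", datetime = utc("2020-01-02 14:00:00"),
      procedure_name = "thoracocentesis", stringsAsFactors = FALSE),
    orders = data.frame(
      episode_id = "E1", start = utc("2020-01-02 08:00:00"),
      end = utc("2020-01-03 08:00:00"), order_type = "urinary_catheter",
      stringsAsFactors = FALSE))
}

# a fully conformant hand-built case
conformant_case <- function() {
  new_case("P1", "E1", as.Date("2020-01-05"), list(
    PS = list(
      admission_datetime = factor_value("admission_datetime", "date",
                                        utc("2020-01-01 10:00:00")),
      hospital_days = factor_value("hospital_days", "integer", 5L)),
    VS = list(body_temperature_max =
                factor_value("body_temperature_max", "real", 38.6, "degC")),
    PN = list(chest_pain = factor_value("chest_pain", "binary", 1))))
}

# random case tuples spanning the factor vocabulary of the packaged rules,
# with deliberate missingness and a mix of early/late onsets
random_cases <- function(n, seed) {
  set.seed(seed)
  registry <- the_registry
  lapply(seq_len(n), function(i) {
    pid <- sprintf("P%03d", sample.int(30, 1))
    as_of <- as.Date("2020-03-01") + sample.int(30, 1)
    back_hours <- sample(1:120, 1)             # admission 1-120 h before day end
    admission <- hai_ts(as_of) + 86400 - back_hours * 3600
    groups <- list(
      PS = list(
        admission_datetime = factor_value("admission_datetime", "date", admission),
        hospital_days = factor_value("hospital_days", "integer",
                                     hospital_days(admission, as_of))),
      DE = list(age = factor_value("age", "integer", sample(1:95, 1))),
      VS = list(), CL = list(), PN = list(), IR = list(), OP = list(),
      MO = list())
    if (runif(1) < 0.8) {
      groups$VS$body_temperature_max <-
        factor_value("body_temperature_max", "real",
                     round(runif(1, 36, 41), 1), "degC")
    }
    numeric_pool <- list(
      pleural_wbc = function() runif(1, 0, 3000),
      urine_wbc = function() runif(1, 0, 100),
      crp = function() runif(1, 0, 60))
    for (fid in names(numeric_pool)) {
      if (runif(1) < 0.6) {
        groups$CL[[fid]] <- factor_value(fid, "real", numeric_pool[[fid]]())
      }
    }
    binary_pool <- list(
      CL = c("has_pct_lab", "urine_wbc_abnormal", "urine_bacteria_abnormal",
             "pleural_micro_positive", "urine_micro_positive",
             "sputum_micro_positive", "wound_micro_positive"),
      PN = c("chest_pain", "urinary_symptoms", "cough_sputum",
             "skin_infection_note"),
      IR = c("ir_pleural_effusion", "ir_pulmonary_infiltrate"))
    for (g in names(binary_pool)) {
      for (fid in binary_pool[[g]]) {
        if (runif(1) < 0.8) {
          groups[[g]][[fid]] <- factor_value(fid, "binary", rbinom(1, 1, 0.4))
        }
      }
    }
    new_case(pid, paste0("EP-", pid), as_of, groups)
  })
}

hai_ts <- function(d) as.POSIXct(paste(format(d), "00:00:00"), tz = "UTC")
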