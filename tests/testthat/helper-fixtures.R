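# compact builders for hand-written scenarios; times given as "HH:MM" on a
# fixed day, or as day offsets via d
t_at <- function(hhmm, day = 0) {
  as.POSIXct(paste0("2003-06-0", day + 1, " ", hhmm, ":00"), tz = "UTC")
}

make_labs <- function(times, values, electrolyte = "potassium",
                      stay_id = 1L, subject_id = 1L) {
  data.frame(subject_id = subject_id, stay_id = stay_id,
             electrolyte = electrolyte, charttime = times, value = values,
             stringsAsFactors = FALSE)
}

make_reps <- function(times, electrolyte = "potassium", stay_id = 1L,
                      subject_id = 1L, dose = 20) {
  data.frame(subject_id = subject_id, stay_id = stay_id,
             electrolyte = electrolyte, ordertime = times, dose = dose,
             stringsAsFactors = FALSE)
}

make_stays <- function(n, age = 50, unit = "MICU") {
  data.frame(stay_id = seq_len(n), subject_id = seq_len(n),
             unit_type = rep_len(unit, n),
             intime = t_at("00:00"), outtime = t_at("00:00", 4),
             age_years = rep_len(age, n), weight_kg = 80,
             stringsAsFactors = FALSE)
}

make_diagnoses <- function(stay_id, code, seq_num = 1L) {
  data.frame(subject_id = stay_id, stay_id = stay_id, icd9_code = code,
             seq_num = seq_num, stringsAsFactors = FALSE)
}

# episodes table with just the fields classification/temporal need
make_episodes <- function(electrolyte, scenario, index_value,
                          index_time = t_at("06:00"),
                          order_time = NULL, followup_value = NA_real_,
                          lab_to_order = NA_real_, order_to_followup = NA_real_) {
  n <- max(length(electrolyte), length(scenario), length(index_value),
           length(lab_to_order), length(followup_value),
           length(order_to_followup))
  if (is.null(order_time))
    order_time <- .POSIXct(ifelse(rep_len(scenario, n) == "NR", NA_real_,
                                  as.numeric(t_at("09:00"))), tz = "UTC")
  data.frame(
    episode_id = seq_len(n),
    stay_id = "1", subject_id = "1",
    electrolyte = rep_len(electrolyte, n),
    scenario = rep_len(scenario, n),
    index_time = rep_len(index_time, n),
    index_value = rep_len(index_value, n),
    index_lab_id = seq_len(n), n_ignored = 0L,
    order_time = rep_len(order_time, n),
    dose = 20,
    lab_to_order_minutes = rep_len(lab_to_order, n),
    followup_time = rep_len(t_at("12:00"), n),
    followup_value = rep_len(followup_value, n),
    followup_lab_id = NA_integer_,
    order_to_followup_minutes = rep_len(order_to_followup, n),
    stringsAsFactors = FALSE)
}
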