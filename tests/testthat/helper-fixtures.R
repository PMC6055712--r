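library(data.table)

# one-product plausibility row with workable defaults
plaus_row <- function(product_code = "P1", drug_class = "drug",
                      qty_min = 1, qty_max = 500, ndd_min = 0.5,
                      ndd_max = 12, dur_min = 1, dur_max = 186,
                      default_qty = 56, default_ndd = 2,
                      default_duration_days = 28) {
  data.table(product_code = product_code, drug_class = drug_class,
             qty_min = qty_min, qty_max = qty_max, ndd_min = ndd_min,
             ndd_max = ndd_max, dur_min = dur_min, dur_max = dur_max,
             default_qty = default_qty, default_ndd = default_ndd,
             default_duration_days = default_duration_days)
}

# therapy rows built from parallel vectors, with NA-friendly defaults
rx_rows <- function(patient_id, product_code = "P1", start_date,
                    qty = NA_real_, ndd = NA_real_, numdays = NA_real_,
                    dose_duration = NA_real_) {
  data.table(patient_id = patient_id, product_code = product_code,
             start_date = start_date, qty = as.numeric(qty),
             ndd = as.numeric(ndd), numdays = as.numeric(numdays),
             dose_duration = as.numeric(dose_duration))
}

episode_rows <- function(start, stop, patient_id = 1L, drug_class = "drug") {
  data.table(patient_id = patient_id, drug_class = drug_class,
             start = as.integer(start), stop = as.integer(stop))
}

# tiny registry with `counts[i]` options at node i (letters a, b, c, ...)
make_registry <- function(counts) {
  nodes <- lapply(seq_along(counts), function(i) {
    list(node_id = as.integer(i), step = "A",
         label = paste("test node", i),
         options = paste0(i, letters[seq_len(counts[i])]))
  })
  structure(list(nodes = nodes), class = "decision_registry")
}

# the worked 12-record example shipped with the package
example_paths <- function() {
  list(
    therapy = system.file("extdata", "therapy_example.csv",
                          package = "rxprep"),
    plausibility = system.file("extdata", "plausibility_example.csv",
                               package = "rxprep"),
    followup = system.file("extdata", "followup_example.csv",
                           package = "rxprep"))
}

read_example <- function() {
  p <- example_paths()
  list(therapy = fread(p$therapy),
       plausibility = fread(p$plausibility),
       followup = fread(p$followup))
}
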