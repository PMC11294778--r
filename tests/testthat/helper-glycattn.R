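# Shared fixtures, built in code.

tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(encoder_layers = 1L, decoder_layers = 1L, heads = 2L,
         hidden_size = 8L, ffn_hidden = 16L, batch_size = 8L,
         iterations = 20L, learning_rate = 1e-3),
    list(...))
  do.call(model_config, args)
}

small_cohort <- function(n = 40, seed = 1, start = "2009-01-01",
                         end = "2012-12-31", ...) {
  generate_cohort(cohort_config(n_patients = n, start_date = start,
                                end_date = end, seed = seed, ...))
}

# Hand-built instance set: values is an n x W matrix with NA at missing.
manual_instances <- function(values, label = rep(FALSE, nrow(values)),
                             threshold = 8.0) {
  structure(list(
    values = values,
    observed = !is.na(values),
    label = label,
    reference_date = rep(as.Date("2013-06-05"), nrow(values)),
    patient_id = sprintf("P%03d", seq_len(nrow(values))),
    history_years = 1L,
    horizon_years = 1L,
    threshold = threshold
  ), class = "instance_set")
}

# Replace the (never-read) values at missing slots by random finite numbers;
# downstream outputs must be bit-identical.
perturb_sentinels <- function(instances, seed = 99) {
  set.seed(seed)
  miss <- !instances$observed
  instances$values[miss] <- stats::runif(sum(miss), -50, 50)
  instances
}
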