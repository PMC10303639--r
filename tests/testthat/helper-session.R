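# Shared synthetic fixtures, generated once per test run and cached.
# small_session(): a 3-trial subject at defaults, used by several files.
# default_run(): the full 15-trial study-conditions run with the fitted
# model, predictions and ablation table (the expensive fixture shared by
# the acceptance tests).

.fixture_env <- new.env(parent = emptyenv())

small_session <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_session(synth_config(n_trials = 3, seed = 42))
  }
  .fixture_env$small
}

small_fit <- function() {
  if (is.null(.fixture_env$small_fit)) {
    ses <- small_session()
    spans <- eval_minute_spans(ses$config)
    set.seed(101)
    .fixture_env$small_fit <- mqrs_fit(
      ses$training$mobile, truth_annotations(ses$training$chest_truth),
      spans, template_ann = truth_annotations(ses$training$truth))
  }
  .fixture_env$small_fit
}

default_run <- function() {
  if (is.null(.fixture_env$default)) {
    cfg <- synth_config(seed = 7)
    ses <- generate_session(cfg)
    spans <- eval_minute_spans(cfg)
    set.seed(11)
    tab <- mqrs_ablation(ses)
    set.seed(11)
    fit <- mqrs_fit(ses$training$mobile,
                    truth_annotations(ses$training$chest_truth), spans,
                    template_ann = truth_annotations(ses$training$truth))
    ref <- truth_minute_durations(ses$testing$truth, spans, channel = "chest")
    est <- predict(fit, ses$testing$mobile, spans, reference = ref)
    .fixture_env$default <- list(config = cfg, session = ses, spans = spans,
                                 fit = fit, estimate = est, ablation = tab,
                                 reference = ref)
  }
  .fixture_env$default
}
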