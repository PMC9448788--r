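# Example fixtures are deterministic for a given (plan, seed); synthesize
# each once per test run and reuse.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- synthesize_dataset(example_plan(name))
  .fixture_cache[[name]]
}

example_names <- paste0("asl00", 1:5)

error_rules <- function(report) {
  unique(report$issues$rule_id[report$issues$severity == "ERROR"])
}

n_errors <- function(report) sum(report$issues$severity == "ERROR")

# Run a cmd_* function, discarding its printed output, returning the code.
capture_exit <- function(expr) {
  code <- NULL
  utils::capture.output(code <- expr)
  code
}

sidecar_value <- function(dataset, name) dataset$asl_sidecar$entries[[name]]
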