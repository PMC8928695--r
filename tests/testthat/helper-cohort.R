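# Memoised phantom cohort and pipeline runs shared by the heavier tests,
# so each is computed once per test session under fixed study conditions.

.memo <- new.env(parent = emptyenv())

studySpec <- function() phantomSpec()   # the default study conditions

studyCohort <- function(n = 10L) {
  key <- paste0("cohort", n)
  if (is.null(.memo[[key]]))
    .memo[[key]] <- generateCohort(studySpec(), n)
  .memo[[key]]
}

studyPipeline <- function(method) {
  key <- paste0("pipe_", method)
  if (is.null(.memo[[key]])) {
    tpl <- phantomTemplateCuboid(studySpec())
    .memo[[key]] <- runPipeline(studyCohort(), method, mracConfig(),
                                template = tpl)
  }
  .memo[[key]]
}
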