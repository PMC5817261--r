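# Shared scaled-down phantom study for the end-to-end tests.  Built once
# on first use and cached for the session; all heavy tests draw from it
# so the cohort is simulated and the reference V-Net trained exactly once.

.study_cache <- new.env(parent = emptyenv())

study_cases <- function() {
  if (is.null(.study_cache$cases)) {
    cfg <- phantom_study_defaults(n = 10L, holdout = 3L)
    .study_cache$cfg <- cfg
    .study_cache$cases <- simulate_cases(cfg$n, cfg$grid, base_seed = 2024L,
                                         config = cfg$phantom,
                                         n_iter = cfg$mlem_iter)
  }
  .study_cache$cases
}

study_cfg <- function() {
  study_cases()
  .study_cache$cfg
}

# schedule shared by the reference V-Net and the close comparisons
study_schedule <- function() {
  sched <- study_cfg()$schedule
  sched$pretrain_iters <- 500L
  sched$max_finetune_iters <- 220L
  sched
}

# the reference V-Net (PET+CT) study result; also the PET+CT arm of the
# model-ordering comparisons (same schedule throughout)
study_vnet <- function() {
  if (is.null(.study_cache$vnet)) {
    cfg <- study_cfg()
    .study_cache$vnet <- run_phantom_study(study_cases(),
                                           holdout = cfg$holdout,
                                           channels = c("ct", "pet"),
                                           base_width = cfg$base_width,
                                           schedule = study_schedule(),
                                           seed = 77L)
  }
  .study_cache$vnet
}
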