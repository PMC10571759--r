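# Shared training fixture: a small synthetic cohort and two networks
# trained under the identical budget (convLSTM fusion vs plain
# concatenation). Training is expensive, so the fixture is computed
# once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

tiny_training_fixture <- function() {
  if (!exists("fix", envir = .fixture_env)) {
    sc <- scene_config(height = 256L, width = 256L, n_lesions = c(1L, 3L),
                       lesion_diameter_mm = c(6, 16), contrast = c(0.15, 0.30),
                       seed = 1L)
    ds <- generate_dataset(10L, 2L, sc)
    man <- split_by_patient(ds$images, c(train = 0.6, val = 0.2, test = 0.2),
                            seed = 1L)
    cs <- build_crop_sets(ds$images, man, side = 128L, final_side = 64L,
                          n_offsets = 3L, seed = 1L)
    tc <- train_config(batch_size = 8L, epochs = 3L, seed = 1L)
    heldout_dice <- function(m) {
      mean(vapply(cs$test, function(cr) {
        pr <- predict(m, cr$image)
        dice_coef(binarize_prob(pr, 0.5), cr$mask)
      }, numeric(1)))
    }
    aku <- fit_akunet(build_model(aku_model_config(
      input_side = 64L, base_filters = 8L, convlstm_grid = c(2L, 2L),
      seed = 1L)), cs$train, cs$val, tc)
    base <- fit_akunet(build_model(aku_model_config(
      input_side = 64L, base_filters = 8L, skip_fusion = "concat",
      seed = 1L)), cs$train, cs$val, tc)
    assign("fix", list(
      dataset = ds, manifest = man, crops = cs,
      aku = aku, baseline = base,
      aku_dice = heldout_dice(aku), baseline_dice = heldout_dice(base)),
      envir = .fixture_env)
  }
  get("fix", envir = .fixture_env)
}
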