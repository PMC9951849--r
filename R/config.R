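# YAML run configuration: one file describes the phantom, the projection
# geometry, the demons settings and the training recipe. Two profiles ship
# with the package: configs/desk.yaml (32^3, small network, 200 samples;
# runs on one CPU) and configs/paper.yaml (128^3, full widths, 6000
# samples split 5400/300/300).

#' Load a run configuration from YAML
#'
#' @param path YAML file; see the files under
#'   `system.file("configs", package = "orthoreg")` for the schema.
#' @return List with `phantom` (`orv_phantom_spec`), `geometry`
#'   (`orv_proj_geometry`), `demons` (`orv_demons_config`) and `train`
#'   (`orv_train_config`).
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  phantom <- do.call(phantom_spec, y$phantom %||% list())
  geometry <- do.call(projection_geometry, y$geometry %||% list())
  demons <- do.call(demons_config, y$demons %||% list())
  tr <- y$train %||% list()
  if (!is.null(tr$loss_weights))
    tr$loss_weights <- do.call(loss_weights, tr$loss_weights)
  if (!is.null(tr$net)) tr$net <- do.call(net_config, tr$net)
  train <- do.call(train_config, tr)
  list(phantom = phantom, geometry = geometry, demons = demons,
       train = train)
}

#' Bundled configuration profiles
#' @param name `"desk"` or `"paper"`.
#' @return Path to the YAML file.
#' @export
config_path <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  system.file("configs", paste0(name, ".yaml"), package = "orthoreg",
              mustWork = TRUE)
}
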