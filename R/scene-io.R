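#' Load a scene configuration from YAML
#'
#' Reads a scene description (a `type: room` or `type: forest` mapping of
#' constructor arguments) from a YAML file or a named preset shipped with
#' the package. Available presets: `room_default`, `forest_default`,
#' `forest_temperate`, `forest_tropical`, `forest_coastal`,
#' `forest_inland`. The forest variants are illustrative contrasts (denser
#' or sparser understory, gap frequency, reflectance), not calibrations to
#' any particular site.
#'
#' @param source Path to a YAML file, or a preset name.
#'
#' @return A [room_scene()] or [forest_scene()].
#' @export
#'
#' @examples
#' load_scene("forest_tropical")
load_scene <- function(source) {
  path <- source
  if (!file.exists(path)) {
    path <- system.file("extdata", "scenes", paste0(source, ".yaml"),
                        package = "metaprop")
    if (!nzchar(path)) {
      stop_validation("no scene file or preset named '%s'", source)
    }
  }
  spec <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop_format("cannot parse %s: %s",
                                                   path, conditionMessage(e)))
  if (is.null(spec$type) || !spec$type %in% c("room", "forest")) {
    stop_validation("scene '%s' must declare type: room or type: forest", source)
  }
  ctor <- if (spec$type == "room") room_scene else forest_scene
  args <- spec[setdiff(names(spec), "type")]
  unknown <- setdiff(names(args), names(formals(ctor)))
  if (length(unknown) > 0) {
    stop_validation("unknown scene key(s) in %s: %s", source,
                    paste(unknown, collapse = ", "))
  }
  do.call(ctor, args)
}

#' List the scene presets shipped with the package
#'
#' @return Character vector of preset names usable with [load_scene()].
#' @export
scene_presets <- function() {
  files <- list.files(system.file("extdata", "scenes", package = "metaprop"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}
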