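#' Write a model to a single JSON file
#'
#' Stores the subnet and head configurations, the initialization seed and
#' every parameter array (as flat numeric vectors plus dimensions) with full
#' double precision, so [read_mfdl()] reproduces the model bit-exactly.
#'
#' @param model an `mfdl_model`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_mfdl <- function(model, path) {
  stopifnot(inherits(model, "mfdl_model"))
  flat <- collect_params(model)
  obj <- list(
    format = "mfdl-model",
    version = 1L,
    seed = model$seed,
    subnet_configs = lapply(model$subnets, function(s) {
      cfg <- unclass(s$config)
      cfg[!vapply(cfg, is.null, logical(1))]
    }),
    head_config = if (is.null(model$head)) NULL else unclass(model$head$config),
    norm = model$norm,
    params = lapply(flat, function(a) {
      list(dim = if (is.matrix(a)) dim(a) else length(a), data = as.vector(a))
    })
  )
  # digits = I(17) serializes doubles with 17 significant digits, which
  # round-trips IEEE doubles bit-exactly
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' Read a model written by [write_mfdl()]
#'
#' @param path file path.
#' @return An `mfdl_model` identical to the one written.
#' @export
read_mfdl <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(obj$format, "mfdl-model"))
    stop("'", path, "' is not a serialized model file")
  configs <- lapply(obj$subnet_configs, function(cfg) {
    do.call(subnet_config, cfg[setdiff(names(cfg), character(0))])
  })
  head_cfg <- if (is.null(obj$head_config)) NULL else
    do.call(head_config, obj$head_config)
  model <- build_mfdl(configs, head_cfg, seed = obj$seed)
  if (!is.null(obj$norm)) {
    num <- function(x) if (is.null(x)) NULL else
      list(center = as.numeric(x$center), scale = as.numeric(x$scale))
    model$norm <- list(inputs = if (is.null(obj$norm$inputs)) NULL else
      lapply(obj$norm$inputs, num), y = num(obj$norm$y))
  }
  flat <- collect_params(model)
  for (nm in names(flat)) {
    p <- obj$params[[nm]]
    if (is.null(p)) stop("parameter '", nm, "' missing from file")
    v <- as.numeric(unlist(p$data))
    dm <- as.integer(unlist(p$dim))
    flat[[nm]] <- if (length(dm) == 2L) matrix(v, dm[1L], dm[2L]) else v
  }
  assign_params(model, flat)
}
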