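# Model archive: a versioned JSON schema holding every layer matrix, head
# parameters, link names, activation, feature names and (for fitted bundles)
# the feature scaling and target encodings. Doubles are encoded as "%.17g"
# strings, which round-trip IEEE doubles exactly, so a load is bitwise
# faithful to the saved model.

num_enc <- function(x) sprintf("%.17g", as.numeric(x))
num_dec <- function(s) as.numeric(s)

enc_layer <- function(l) list(dim = dim(l$W), W = num_enc(l$W), b = num_enc(l$b))
dec_layer <- function(e) {
  dense_layer(matrix(num_dec(e$W), e$dim[[1L]], e$dim[[2L]]), num_dec(e$b))
}

enc_subnet <- function(s) list(role = s$role, activation = s$activation,
                               layers = lapply(s$layers, enc_layer))
dec_subnet <- function(e) subnetwork(lapply(e$layers, dec_layer),
                                     role = e$role, activation = e$activation)

enc_head <- function(h) list(dim = dim(h$W), W = num_enc(h$W),
                             b = num_enc(h$b), link = h$link)
dec_head <- function(e) {
  task_head(matrix(num_dec(e$W), e$dim[[1L]], e$dim[[2L]]), num_dec(e$b),
            link = e$link)
}

#' Save a model or fit to a JSON archive
#'
#' @param x A `gatan_model` or `gatan_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gatan <- function(x, path) {
  if (inherits(x, "gatan_fit")) {
    payload <- list(schema = "gatan-fit", version = 1L,
                    model = model_payload(x$model),
                    scaling = if (!is.null(x$scaling)) {
                      list(mean = num_enc(x$scaling$mean),
                           sd = num_enc(x$scaling$sd))
                    },
                    encoding = x$encoding,
                    feature_names = x$feature_names)
  } else if (inherits(x, "gatan_model")) {
    payload <- c(list(schema = "gatan-model", version = 1L), model_payload(x))
  } else {
    stop("write_gatan: expected a gatan_model or gatan_fit", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       pretty = FALSE)
  invisible(path)
}

model_payload <- function(model) {
  list(shared = enc_subnet(model$shared),
       primary = enc_subnet(model$primary),
       aux = lapply(model$aux, enc_subnet),
       primary_head = enc_head(model$primary_head),
       aux_heads = lapply(model$aux_heads, enc_head),
       feature_names = as.list(model$feature_names),
       hidden_dims = as.list(model$hidden_dims))
}

model_from_payload <- function(p) {
  structure(list(shared = dec_subnet(p$shared),
                 primary = dec_subnet(p$primary),
                 aux = lapply(p$aux, dec_subnet),
                 primary_head = dec_head(p$primary_head),
                 aux_heads = lapply(p$aux_heads, dec_head),
                 feature_names = unlist(p$feature_names),
                 hidden_dims = as.integer(unlist(p$hidden_dims))),
            class = "gatan_model")
}

#' Load a model or fit from a JSON archive
#'
#' @param path Path written by [write_gatan()].
#' @return A `gatan_model` or `gatan_fit`, bitwise identical to the saved
#'   object's parameters.
#' @export
read_gatan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  schema <- p$schema %||% ""
  if (schema == "gatan-model") {
    model_from_payload(p)
  } else if (schema == "gatan-fit") {
    enc <- p$encoding
    enc$aux <- as.character(unlist(enc$aux))
    enc$aux_types <- as.character(unlist(enc$aux_types))
    enc$levels <- lapply(enc$levels, function(l) {
      if (is.null(l)) NULL else as.character(unlist(l))
    })
    structure(list(model = model_from_payload(p$model),
                   report = NULL,
                   scaling = if (!is.null(p$scaling)) {
                     list(mean = num_dec(unlist(p$scaling$mean)),
                          sd = num_dec(unlist(p$scaling$sd)))
                   },
                   encoding = enc,
                   feature_names = unlist(p$feature_names),
                   train_X = NULL),
              class = "gatan_fit")
  } else {
    stop("read_gatan: unrecognized archive schema '", schema, "'",
         call. = FALSE)
  }
}
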