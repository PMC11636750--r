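# Image and model I/O: 8-bit grayscale PNG, CSV matrices, JSON model
# containers, and dataset manifests.

#' Write an image matrix as 8-bit grayscale PNG
#'
#' @param img Numeric matrix in \[0, 1\] (masks may be 0/1 integers).
#' @param path Output file path.
#' @export
write_image_png <- function(img, path) {
  assert_image(img)
  png::writePNG(pmin(pmax(img, 0), 1), target = path)
  invisible(path)
}

#' Read a grayscale PNG as an image matrix in \[0, 1\]
#'
#' Color images are averaged over channels.
#'
#' @param path PNG file path.
#' @return Numeric matrix.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  a
}

#' Write a phantom dataset to disk
#'
#' Images and masks as PNG plus a CSV manifest (`image`, `mask`, `label`,
#' `split`).
#'
#' @param ds A `ct_dataset` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ct_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(ds$samples)
  split_of <- integer(n)
  for (s in names(ds$split)) split_of[ds$split[[s]]] <- s
  rows <- lapply(seq_len(n), function(i) {
    ip <- file.path(dir, sprintf("img_%04d.png", i))
    mp <- file.path(dir, sprintf("mask_%04d.png", i))
    write_image_png(ds$samples[[i]]$image, ip)
    write_image_png(ds$samples[[i]]$mask, mp)
    tibble::tibble(image = basename(ip), mask = basename(mp),
                   label = ds$labels[i], split = split_of[i])
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Serialize a DBN segmenter to a JSON container
#'
#' @param model A `dbn_model`.
#' @param path Output path.
#' @export
write_dbn <- function(model, path) {
  stopifnot(inherits(model, "dbn_model"))
  obj <- list(
    stack = lapply(model$stack, function(p) list(
      WT = p$WT, b_vis = p$b_vis, b_hid = p$b_hid, kind = p$kind
    )),
    head = model$head, patch_size = model$patch_size, stride = model$stride,
    threshold = model$threshold, standardize = as.list(model$standardize),
    epochs = model$epochs
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a DBN segmenter from its JSON container
#'
#' @param path Path written by [write_dbn()].
#' @return A `dbn_model`.
#' @export
read_dbn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  stack <- lapply(obj$stack, function(p) {
    structure(list(WT = as.matrix(p$WT), b_vis = as.numeric(p$b_vis),
                   b_hid = as.numeric(p$b_hid), kind = p$kind),
              class = "rbm_params")
  })
  std <- unlist(obj$standardize)
  structure(list(stack = stack, head = as.numeric(obj$head),
                 patch_size = as.integer(obj$patch_size),
                 stride = as.integer(obj$stride),
                 threshold = obj$threshold,
                 standardize = c(mu = unname(std["mu"]), sd = unname(std["sd"])),
                 epochs = obj$epochs),
            class = "dbn_model")
}

#' Serialize a GBDT model as JSON trees
#'
#' @param model A `gbdt_model`.
#' @param path Output path.
#' @export
write_gbdt <- function(model, path) {
  stopifnot(inherits(model, "gbdt_model"))
  obj <- list(base_score = model$base_score,
              params = unclass(model$params),
              features = model$features,
              trees = model$trees)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a GBDT model from JSON
#'
#' @param path Path written by [write_gbdt()].
#' @return A `gbdt_model`.
#' @export
read_gbdt <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  params <- structure(obj$params, class = "gbdt_params")
  trees <- lapply(obj$trees, function(tr) {
    lapply(tr, function(nd) {
      nd$is_leaf <- isTRUE(nd$is_leaf)
      nd
    })
  })
  structure(list(trees = trees, base_score = obj$base_score, params = params,
                 features = obj$features),
            class = "gbdt_model")
}
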