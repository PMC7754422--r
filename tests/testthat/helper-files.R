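# temp-file helpers scoped to the calling test

withr_local_file <- function(name, env = parent.frame()) {
  path <- file.path(tempdir(), paste0(sample.int(1e6, 1), "-", name))
  withr::defer(unlink(path), envir = env)
  path
}

withr_local_dir_path <- function(env = parent.frame()) {
  path <- file.path(tempdir(), paste0("out-", sample.int(1e6, 1)))
  dir.create(path, recursive = TRUE)
  withr::defer(unlink(path, recursive = TRUE), envir = env)
  path
}
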