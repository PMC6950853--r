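# Shared fixtures, all built in code.

# Deterministic library of small molecules covering the structural tasks:
# halogen/nitrile carriers, CF3 carriers, and 0/1/2/3 aromatic-ring systems.
toy_smiles_library <- function() {
  c(
    # 1 aromatic ring, no halogens / CN / CF3
    "Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1", "COc1ccccc1",
    "OCc1ccccc1", "NCc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
    # exactly 2 aromatic rings
    "c1ccc(-c2ccccc2)cc1", "c1ccc(Cc2ccccc2)cc1", "c1ccc(Oc2ccccc2)cc1",
    "c1ccc(CCc2ccccc2)cc1", "c1ccc2ccccc2c1", "Cc1ccc(-c2ccccc2)cc1",
    "c1ccc(Nc2ccccc2)cc1", "c1ccc(COc2ccccc2)cc1",
    # 3 aromatic rings
    "c1ccc(-c2ccc(-c3ccccc3)cc2)cc1", "C(c1ccccc1)(c1ccccc1)c1ccccc1",
    "c1ccc2cc3ccccc3cc2c1", "c1ccc2c(c1)ccc1ccccc21",
    "N(c1ccccc1)(c1ccccc1)c1ccccc1",
    # chlorides
    "CCCl", "CCCCl", "Clc1ccccc1", "ClCc1ccccc1", "CC(C)Cl", "ClCCCl",
    # fluorides (not CF3)
    "CCF", "Fc1ccccc1", "FCc1ccccc1", "CC(C)F",
    # iodides
    "CCI", "Ic1ccccc1",
    # nitriles (the CN group)
    "CC#N", "N#Cc1ccccc1", "CCC#N", "N#CCc1ccccc1", "CC(C)C#N",
    # CF3 carriers without CN
    "FC(F)(F)C", "FC(F)(F)c1ccccc1", "FC(F)(F)CC", "OC(=O)C(F)(F)F",
    "FC(F)(F)Cc1ccccc1",
    # acyclic, halogen-free
    "CC", "CCC", "CCCC", "CCCCC", "CC(C)C", "CCO", "CCCO", "CC(C)O",
    "CCOCC", "CCN"
  )
}

halogen_patterns <- function() c("[!#1]Cl", "[!#1]F", "[!#1]I", "C#N")

# small networks + batches for loss/gradient tests
tiny_gan_fixture <- function(d = 4L, n = 6L, seed = 7L) {
  withr::local_seed(seed)
  list(
    G = molcycle:::new_generator(d, generator_spec("structural", units = d),
                                 "gaussian"),
    F = molcycle:::new_generator(d, generator_spec("structural", units = d),
                                 "gaussian"),
    D_X = molcycle:::new_discriminator(
      d, discriminator_spec(layer_sizes = c(5L, 3L, 1L))),
    D_Y = molcycle:::new_discriminator(
      d, discriminator_spec(layer_sizes = c(5L, 3L, 1L))),
    x = matrix(stats::rnorm(n * d), n, d),
    y = matrix(stats::rnorm(n * d), n, d),
    d = d, n = n
  )
}

# small, fast synthetic task for trainer unit tests
quick_task_spec <- function(seed = 1L) {
  toy_task_spec(dimension = 2L, n_train = 200L, n_test = 50L, seed = seed)
}

# an affine latent map usable wherever a trained generator is expected
shift_generator <- function(delta) {
  function(z) z + delta
}
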