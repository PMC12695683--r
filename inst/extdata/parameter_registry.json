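{
  "schema": "rtimagerisk-registry-1",
  "note": "Literature stand-in radiobiological parameters. Every value is a cited placeholder intended to be overridden with institution-specific fits; see load_parameter_registry().",
  "organs": {
    "breast": {
      "ntcp": {"model": "logistic", "d50": 55.0, "gamma50": 3.0,
               "source": "Emami et al. 1991 IJROBP 21:109 (derived stand-in, late breast fibrosis)"},
      "ear": {"ear0": 8.2, "alpha_prime": 0.085, "gamma_e": -0.037, "gamma_a": 1.7,
              "e0": 30, "a0": 70,
              "source": "Schneider et al. 2011 Theor Biol Med Model 8:27 (breast carcinoma)"}
    },
    "lung": {
      "ntcp": {"model": "logistic", "d50": 30.8, "gamma50": 0.97,
               "source": "Kwa et al. 1998 IJROBP 42:1 / QUANTEC mean-lung-dose pneumonitis fit (stand-in)"},
      "ear": {"ear0": 7.5, "alpha_prime": 0.085, "gamma_e": -0.024, "gamma_a": 2.38,
              "e0": 30, "a0": 70,
              "source": "Schneider et al. 2011 / BEIR VII Table 12D-1 lung (stand-in)"}
    },
    "heart": {
      "ntcp": {"model": "lkb", "d50": 50.6, "m": 0.13, "n": 0.64,
               "source": "Martel et al. 1998 IJROBP 40:155 (pericarditis LKB fit)"},
      "ear": {"ear0": 4.0, "alpha_prime": 0.085, "gamma_e": -0.024, "gamma_a": 2.38,
              "e0": 30, "a0": 70,
              "source": "BEIR VII 'other solid' coefficient (stand-in for mediastinal soft tissue)"}
    },
    "rectum": {
      "ntcp": {"model": "lkb", "d50": 76.9, "m": 0.13, "n": 0.09,
               "source": "Michalski et al. 2010 IJROBP 76:S123 (QUANTEC rectal LKB)"},
      "ear": {"ear0": 7.2, "alpha_prime": 0.085, "gamma_e": -0.024, "gamma_a": 2.38,
              "e0": 30, "a0": 70,
              "source": "BEIR VII colorectal-derived stand-in"}
    },
    "bladder": {
      "ntcp": {"model": "logistic", "d50": 80.0, "gamma50": 2.0,
               "source": "Emami et al. 1991 IJROBP 21:109 (derived stand-in, bladder contracture)"},
      "ear": {"ear0": 3.8, "alpha_prime": 0.085, "gamma_e": -0.024, "gamma_a": 2.38,
              "e0": 30, "a0": 70,
              "source": "Schneider et al. 2011 / BEIR VII bladder (stand-in)"}
    },
    "bowel": {
      "ntcp": {"model": "logistic", "d50": 55.0, "gamma50": 2.0,
               "source": "Emami et al. 1991 IJROBP 21:109 (derived stand-in, small-bowel obstruction)"},
      "ear": {"ear0": 6.3, "alpha_prime": 0.085, "gamma_e": -0.024, "gamma_a": 2.38,
              "e0": 30, "a0": 70,
              "source": "BEIR VII Table 12D-1 colon (stand-in)"}
    },
    "parotid": {
      "ntcp": {"model": "lkb", "d50": 39.9, "m": 0.40, "n": 1.0,
               "source": "Deasy et al. 2010 IJROBP 76:S58 (QUANTEC xerostomia LKB)"},
      "ear": {"ear0": 0.7, "alpha_prime": 0.085, "gamma_e": -0.024, "gamma_a": 2.38,
              "e0": 30, "a0": 70,
              "source": "Schneider et al. 2011 salivary gland (stand-in)"}
    },
    "spinal_cord": {
      "ntcp": {"model": "logistic", "d50": 66.5, "gamma50": 1.9,
               "source": "Schultheiss 2008 IJROBP 71:1455 (cervical myelopathy logistic fit)"},
      "ear": {"ear0": 0.9, "alpha_prime": 0.085, "gamma_e": -0.024, "gamma_a": 2.38,
              "e0": 30, "a0": 70,
              "source": "BEIR VII CNS-derived stand-in"}
    },
    "brainstem": {
      "ntcp": {"model": "logistic", "d50": 65.0, "gamma50": 2.4,
               "source": "Mayo et al. 2010 IJROBP 76:S36 (QUANTEC brainstem, derived stand-in)"},
      "ear": {"ear0": 0.9, "alpha_prime": 0.085, "gamma_e": -0.024, "gamma_a": 2.38,
              "e0": 30, "a0": 70,
              "source": "BEIR VII CNS-derived stand-in"}
    },
    "optic_nerve": {
      "ntcp": {"model": "logistic", "d50": 65.0, "gamma50": 2.0,
               "source": "Mayo et al. 2010 IJROBP 76:S28 (QUANTEC optic apparatus, derived stand-in)"},
      "ear": {"ear0": 0.9, "alpha_prime": 0.085, "gamma_e": -0.024, "gamma_a": 2.38,
              "e0": 30, "a0": 70,
              "source": "BEIR VII CNS-derived stand-in"}
    }
  }
}
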