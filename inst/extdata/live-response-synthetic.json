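{
  "comment": "Synthetic recorded response of a target-annotation GraphQL query; hand-written test fixture, not real platform data.",
  "data": {
    "targets": [
      {
        "id": "ENSG00000000001",
        "approvedSymbol": "SYNA",
        "approvedName": "Synthetic receptor A",
        "proteinIds": [
          {"id": "P10001", "source": "uniprot_swissprot"},
          {"id": "A0A001", "source": "uniprot_trembl"}
        ],
        "associatedDiseases": {"count": 321},
        "tractability": [
          {"modality": "SMALL_MOLECULE", "label": "Approved Drug", "value": true},
          {"modality": "SMALL_MOLECULE", "label": "Structure with Ligand", "value": true},
          {"modality": "SMALL_MOLECULE", "label": "High-Quality Pocket", "value": true},
          {"modality": "ANTIBODY", "label": "Advanced Clinical", "value": true},
          {"modality": "ANTIBODY", "label": "UniProt loc med conf", "value": true},
          {"modality": "PROTAC", "label": "Phase 1 Clinical", "value": false},
          {"modality": "OTHER", "label": "Approved Drug", "value": false}
        ],
        "subcellularLocations": [{"location": "Cell membrane"}],
        "safetyLiabilities": [{"event": "cardiac arrhythmia"}, {"event": "hepatotoxicity"}],
        "knownDrugs": {
          "uniqueDrugs": 3,
          "rows": [
            {"phase": 4, "mechanismOfAction": "inhibitor", "drug": {"id": "CHEMBL000001", "name": "synthadrug", "drugType": "small molecule", "isApproved": true}},
            {"phase": 2, "mechanismOfAction": "inhibitor", "drug": {"id": "CHEMBL000001", "name": "synthadrug", "drugType": "small molecule", "isApproved": true}},
            {"phase": 3, "mechanismOfAction": "antagonist", "drug": {"id": "CHEMBL000002", "name": "synthbmab", "drugType": "antibody", "isApproved": false}},
            {"phase": 1, "mechanismOfAction": "modulator", "drug": {"id": "CHEMBL000003", "name": "synthcpd", "drugType": "small molecule", "isApproved": false}}
          ]
        }
      },
      {
        "id": "ENSG00000000002",
        "approvedSymbol": "SYNB",
        "approvedName": "Synthetic kinase B",
        "proteinIds": [{"id": "P10002", "source": "uniprot_swissprot"}],
        "associatedDiseases": {"count": 12},
        "tractability": [],
        "subcellularLocations": [],
        "safetyLiabilities": [],
        "knownDrugs": {"uniqueDrugs": 0, "rows": []}
      }
    ]
  }
}
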