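{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ontoreg form-model bundle",
  "description": "Renderable description of an application: menus, forms, widgets, grid positions and value constraints, compiled from the application ontology.",
  "type": "object",
  "required": ["schema_version", "application", "case_root", "menu", "forms"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "application": {"type": "string", "format": "iri"},
    "case_root": {"type": ["string", "null"]},
    "menu": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["label", "property", "target"],
        "properties": {
          "label": {"type": "string"},
          "property": {"type": "string"},
          "target": {"type": "string"}
        }
      }
    },
    "forms": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["data_structure", "local", "reportable", "fields"],
        "properties": {
          "data_structure": {"type": "string"},
          "local": {"type": "string"},
          "reportable": {"type": "boolean"},
          "description_columns": {"type": "array", "items": {"type": "string"}},
          "fields": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["property", "local", "widget", "row", "column",
                           "facets", "is_object"],
              "properties": {
                "property": {"type": "string"},
                "local": {"type": "string"},
                "widget": {"enum": ["Checkbox", "Combobox", "Graphic",
                                    "HyperlinkProperty", "ImageProperty",
                                    "LiteralProperty",
                                    "MultilineStringProperty", "RadioButton",
                                    "SingleCell", "Password", "SubForm"]},
                "row": {"type": "integer", "minimum": 1},
                "column": {"type": "integer", "minimum": 1},
                "facets": {
                  "type": "object",
                  "required": ["description", "mandatory", "id",
                               "edition_disabled", "directly_dependent"],
                  "additionalProperties": {"type": "boolean"}
                },
                "range": {"type": ["string", "null"]},
                "value_tag": {"type": ["string", "null"],
                              "enum": ["string", "integer", "float",
                                       "boolean", "date", "datetime", null]},
                "is_object": {"type": "boolean"},
                "options": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["iri", "label", "rank"],
                    "properties": {
                      "iri": {"type": "string"},
                      "label": {"type": "string"},
                      "code": {"type": ["string", "null"]},
                      "rank": {"type": "integer"}
                    }
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
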